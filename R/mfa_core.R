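#' Principal component analysis by singular value decomposition
#'
#' Eigenvalues are squared singular values divided by (n - 1), so with
#' autoscaled input they sum to the number of variables. Reconstruction from
#' all components reproduces the input to numerical precision.
#'
#' @param x Numeric column-centered samples x features matrix (>= 2 rows).
#' @param n_comp Number of components to return (default: full rank).
#' @return List with `eigenvalues`, `scores` (samples x components,
#'   `U %*% D`), `loadings` (features x components, `V`), and
#'   `variance_explained` in percent of total variance.
#' @export
pca <- function(x, n_comp = NULL) {
  x <- as.matrix(x)
  if (nrow(x) < 2) stop("pca needs >= 2 samples")
  if (max(abs(colMeans(x))) > 1e-8 * max(1, max(abs(x))))
    stop("pca expects a column-centered matrix")
  s <- svd(x)
  eig <- s$d^2 / (nrow(x) - 1)
  rank <- sum(s$d > s$d[1] * 1e-12)
  if (rank == 0) stop("pca: zero matrix (no variance)")
  k <- if (is.null(n_comp)) rank else min(n_comp, rank)
  scores <- s$u[, seq_len(k), drop = FALSE] %*%
    diag(s$d[seq_len(k)], k, k)
  loadings <- s$v[, seq_len(k), drop = FALSE]
  # reproducible orientation: largest-|loading| entry positive per component
  for (a in seq_len(k)) {
    j <- which.max(abs(loadings[, a]))
    if (loadings[j, a] < 0) {
      loadings[, a] <- -loadings[, a]
      scores[, a] <- -scores[, a]
    }
  }
  rownames(scores) <- rownames(x)
  rownames(loadings) <- colnames(x)
  colnames(scores) <- colnames(loadings) <- paste0("dim", seq_len(k))
  # eigenvalues are reported for the full spectrum; scores/loadings are
  # truncated to the requested (or numerically meaningful) components
  list(eigenvalues = eig, scores = scores, loadings = loadings,
       variance_explained = 100 * eig / sum(eig))
}

#' MFA block weight: inverse first eigenvalue
#'
#' Each variable block is weighted by the inverse of the eigenvalue of the
#' first principal component of a PCA on that block alone, so that after
#' multiplying the block by the square root of the weight its first-axis
#' inertia equals 1 and every source brings the same initial amount of
#' information to the global analysis.
#'
#' @param x Autoscaled (or at least centered) block matrix.
#' @return The scalar weight 1 / lambda_1.
#' @export
block_weight <- function(x) {
  x <- as.matrix(x)
  l1 <- svd(x, nu = 0, nv = 0)$d[1]^2 / (nrow(x) - 1)
  if (l1 <= 1e-12) stop("degenerate block: first eigenvalue is 0")
  1 / l1
}

#' Encode a qualitative variable for MFA
#'
#' Standard MFA treatment of a categorical variable: the sample x level
#' indicator matrix is rescaled column-wise by the inverse square root of
#' each level's proportion and then column-centered, which is the
#' correspondence-analysis metric for a single qualitative variable.
#'
#' @param classes Factor or character vector, one level per sample.
#' @return Centered encoded matrix (samples x levels).
#' @export
encode_qualitative <- function(classes) {
  classes <- as.factor(classes)
  if (nlevels(classes) < 2) stop("qualitative variable needs >= 2 levels")
  if (any(table(classes) == 0)) stop("qualitative level with zero samples")
  ind <- stats::model.matrix(~ classes - 1)
  colnames(ind) <- levels(classes)
  prop <- colMeans(ind)
  enc <- sweep(ind, 2, sqrt(prop), "/")
  sweep(enc, 2, colMeans(enc))
}

#' Multiple Factor Analysis over omics blocks
#'
#' Global PCA of the column-concatenation of the blocks, each rescaled by
#' the square root of its inverse-first-eigenvalue weight, optionally with a
#' qualitative class variable included as an additional (active) block. The
#' class block participates in the solution by default; with
#' `class_active = FALSE` it is only projected afterwards.
#'
#' Contributions follow the standard convention: variable j's contribution
#' to dimension s is 100 times its squared loading in the weighted global
#' PCA (these sum to 100% per dimension); a block's contribution is the sum
#' over its variables.
#'
#' @param blocks Named list of preprocessed (pair-centered, autoscaled)
#'   matrices or [omics_block()]s sharing sample order.
#' @param classes Optional per-sample class labels (qualitative block).
#' @param n_dims Number of dimensions to report (truncated to rank with a
#'   warning if too large).
#' @param class_active Include the class block in the solution (default) or
#'   as supplementary projection only.
#' @return An `mfa_result`: `eigenvalues`, `scores`,
#'   `variance_explained`, `block_weights`, `block_contributions` (blocks x
#'   dims, percent), `variable_contributions` (features x dims, percent).
#' @export
mfa_fit <- function(blocks, classes = NULL, n_dims = 5, class_active = TRUE) {
  mats <- lapply(blocks, function(b)
    if (inherits(b, "omics_block")) b$matrix else as.matrix(b))
  ns <- unique(vapply(mats, nrow, 1L))
  if (length(ns) != 1) stop("mfa_fit: blocks disagree on sample count")
  if (!is.null(classes) && length(classes) != ns)
    stop("mfa_fit: classes length must equal sample count")

  if (!is.null(classes) && class_active) {
    enc <- encode_qualitative(classes)
    colnames(enc) <- paste0("class:", colnames(enc))
    mats$classes <- enc
  }
  weights <- vapply(mats, block_weight, numeric(1))
  weighted <- Map(function(m, w) m * sqrt(w), mats, weights)
  global <- do.call(cbind, weighted)
  blk_of_col <- rep(names(mats), vapply(mats, ncol, 1L))

  fit <- pca(global)
  k <- min(n_dims, ncol(fit$scores))
  if (k < n_dims)
    warning("mfa_fit: n_dims truncated to rank ", k)
  contrib <- 100 * fit$loadings[, seq_len(k), drop = FALSE]^2
  blockc <- rowsum(contrib, blk_of_col)[unique(blk_of_col), , drop = FALSE]

  res <- list(eigenvalues = fit$eigenvalues[seq_len(k)],
              scores = fit$scores[, seq_len(k), drop = FALSE],
              variance_explained = fit$variance_explained[seq_len(k)],
              block_weights = weights,
              block_contributions = blockc,
              variable_contributions = contrib,
              n_dims = k)
  if (!is.null(classes) && !class_active) {
    enc <- encode_qualitative(classes)
    res$class_projection <- t(enc) %*% fit$scores[, seq_len(k), drop = FALSE] /
      nrow(enc)
  }
  structure(res, class = "mfa_result")
}

#' @export
print.mfa_result <- function(x, ...) {
  cat("Multiple Factor Analysis:", nrow(x$scores), "samples,",
      length(x$block_weights), "blocks,", x$n_dims, "dimensions\n")
  cat("Variance explained (%):",
      paste(sprintf("%.1f", x$variance_explained), collapse = ", "), "\n")
  cat("Block contributions to dim1 (%):\n")
  print(round(x$block_contributions[, 1], 1))
  invisible(x)
}
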