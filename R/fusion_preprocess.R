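#' Day-pair centering of an omics block
#'
#' Subtracts from each sample the mean of its day's control/treated pair,
#' feature by feature. Because the two members of a pair were processed on
#' the same day, this removes the additive day batch effect exactly: after
#' centering, each day-pair's two rows sum to the zero vector, and what is
#' left is the within-pair contrast that carries the treatment signal.
#'
#' @param block An [omics_block()] (or plain matrix with sample rownames).
#' @param design Design rows covering exactly the block's samples; every day
#'   in scope must contain one control and one treated sample.
#' @return The block with its matrix pair-centered (same class as input).
#' @export
pair_center <- function(block, design) {
  x <- if (inherits(block, "omics_block")) block$matrix else as.matrix(block)
  if (anyNA(x)) {
    bad <- which(is.na(x), arr.ind = TRUE)[1, ]
    stop("missing intensities are not supported: NA at sample '",
         rownames(x)[bad[1]], "', feature '", colnames(x)[bad[2]], "'")
  }
  design <- design[match(rownames(x), design$sample_id), , drop = FALSE]
  if (anyNA(design$sample_id))
    stop("pairing error: design is missing samples present in the block")
  check_pairing(design)
  for (d in unique(design$day)) {
    rows <- which(design$day == d)
    m <- colMeans(x[rows, , drop = FALSE])
    x[rows, ] <- sweep(x[rows, , drop = FALSE], 2, m)
  }
  if (inherits(block, "omics_block")) {
    block$matrix <- x
    block
  } else x
}

#' Autoscale a feature matrix
#'
#' Global centering and normalization to unit variance (n-1 denominator).
#' Columns that are constant (zero variance) carry no discriminant
#' information and would break unit-variance scaling; they are dropped with
#' a warning and the drop recorded.
#'
#' @param x Numeric samples x features matrix (>= 2 rows).
#' @return A list: `matrix` (scaled), `scaling_record` with per-feature
#'   `center` and `scale` of the retained columns and `dropped` (ids of
#'   removed constant columns). The record back-transforms exactly:
#'   `sweep(sweep(scaled, 2, scale, "*"), 2, center, "+")`.
#' @export
autoscale <- function(x) {
  x <- as.matrix(x)
  if (nrow(x) < 2) stop("autoscale needs >= 2 samples")
  if (anyNA(x)) stop("missing intensities are not supported (NA in matrix)")
  n <- nrow(x)
  ctr <- colMeans(x)
  sc <- sqrt(pmax(colSums(x^2) - n * ctr^2, 0) / (n - 1))
  constant <- sc <= .Machine$double.eps^0.5 * pmax(abs(ctr), 1)
  if (all(constant)) stop("autoscale: all columns constant, empty output")
  if (any(constant)) {
    warning("autoscale: dropping ", sum(constant), " constant column(s): ",
            paste(utils::head(colnames(x)[constant], 5), collapse = ", "),
            if (sum(constant) > 5) ", ..." else "")
  }
  keep <- !constant
  scaled <- sweep(sweep(x[, keep, drop = FALSE], 2, ctr[keep]), 2,
                  sc[keep], "/")
  list(matrix = scaled,
       scaling_record = list(center = ctr[keep], scale = sc[keep],
                             dropped = colnames(x)[constant]))
}

# Internal: apply a training scaling_record to new data (drops the same
# columns, uses training center/scale). Used by cross-validation.
apply_scaling <- function(x, record) {
  x <- x[, names(record$center), drop = FALSE]
  sweep(sweep(x, 2, record$center), 2, record$scale, "/")
}

#' Low-level fusion of omics blocks
#'
#' Column-wise concatenation of the blocks' matrices into one fused dataset,
#' after aligning all blocks to a common sample order. Blocks are laid out
#' in the deterministic order lipidomics, metabolomics, proteomics, then any
#' others alphabetically. Values are preserved bit-exactly; only the layout
#' changes.
#'
#' @param blocks Named list of [omics_block()]s sharing one sample set.
#' @param design Optional design rows; used to record the day pairing.
#' @return A list of class `fused_dataset`: `matrix`, `block_index` (named
#'   character vector feature -> block), `sample_ids`, and `pairing` (day ->
#'   sample ids) when a design is given.
#' @export
fuse <- function(blocks, design = NULL) {
  if (length(blocks) == 0) stop("fuse: no blocks given")
  canonical <- c("lipidomics", "metabolomics", "proteomics")
  nm <- names(blocks)
  ord <- c(intersect(canonical, nm), sort(setdiff(nm, canonical)))
  blocks <- blocks[ord]

  ref <- sort(blocks[[1]]$sample_ids)
  for (b in blocks) {
    if (!setequal(b$sample_ids, ref))
      stop("alignment error: block '", b$block_name,
           "' sample set differs; offending ids: ",
           paste(union(setdiff(b$sample_ids, ref), setdiff(ref, b$sample_ids)),
                 collapse = ", "))
  }
  mats <- lapply(blocks, function(b) b$matrix[ref, , drop = FALSE])
  fusedm <- do.call(cbind, mats)
  block_index <- stats::setNames(
    rep(names(blocks), vapply(blocks, function(b) length(b$feature_ids), 1L)),
    unlist(lapply(blocks, function(b) b$feature_ids), use.names = FALSE))
  if (anyDuplicated(names(block_index)))
    stop("fuse: feature ids collide across blocks")
  colnames(fusedm) <- names(block_index)

  pairing <- NULL
  if (!is.null(design)) {
    d <- design[match(ref, design$sample_id), , drop = FALSE]
    pairing <- split(d$sample_id, d$day)
  }
  structure(list(matrix = fusedm, block_index = block_index,
                 sample_ids = ref, pairing = pairing),
            class = "fused_dataset")
}

#' Preprocess one analysis set: pair-center then autoscale then fuse
#'
#' Convenience wrapper running the preprocessing chain in its fixed order:
#' day-pair centering per block, low-level fusion, then global autoscaling
#' over the analysis set. Pair-centering precedes autoscaling so the
#' variance normalized to 1 is the within-pair variance that discriminant
#' modelling works on.
#'
#' @param blocks Named list of [omics_block()]s.
#' @param design Design rows for the analysis set (e.g. the 12 samples of one
#'   time x site, or the 24 samples of one site).
#' @return A `fused_dataset` whose `matrix` is pair-centered and autoscaled,
#'   with `scaling_record` attached.
#' @export
preprocess_fused <- function(blocks, design) {
  centered <- lapply(blocks, pair_center, design = design)
  fused <- fuse(centered, design)
  sc <- autoscale(fused$matrix)
  fused$matrix <- sc$matrix
  fused$scaling_record <- sc$scaling_record
  fused$block_index <- fused$block_index[colnames(sc$matrix)]
  fused
}
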