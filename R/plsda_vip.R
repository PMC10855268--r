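#' Two-class PLS-DA by NIPALS
#'
#' Partial least squares regression on a class-membership response coded
#' control = +1, treated = -1. Latent variables (LVs) are extracted by
#' NIPALS with X deflation: for LV a, the weight vector is proportional to
#' the covariance direction `X' y` of the current residual matrix
#' (normalized to unit length), scores are `t = X w`, X-loadings
#' `p = X' t / t' t` and the Y-loading `q = y' t / t' t`. The regression
#' vector for the original variables is `b = W (P' W)^-1 q`.
#'
#' @param X Preprocessed (pair-centered, autoscaled) samples x features
#'   matrix.
#' @param y Class labels: factor/character with levels control/treated, or
#'   numeric +1/-1.
#' @param n_lv Number of latent variables, at most `rank(X)`.
#' @return A `plsda_model`: `weights` (W, unit-norm columns), `x_loadings`
#'   (P), `scores` (T, mutually orthogonal columns), `y_loadings` (q),
#'   `coefficients` (b), `ssy` (Y-variance explained per LV), `y_coding`,
#'   `n_lv`, `feature_ids`.
#' @param y_coding Numeric coding of the two classes; the default codes
#'   control as +1 and treated as -1. Flipping the coding flips the sign of
#'   every coefficient but not the model's interpretations.
#' @export
plsda_fit <- function(X, y, n_lv = 1, y_coding = c(control = 1, treated = -1)) {
  X <- as.matrix(X)
  y <- code_response(y, y_coding)
  if (length(unique(y)) < 2) stop("plsda_fit: single-class response")
  if (nrow(X) != length(y)) stop("plsda_fit: X and y disagree on samples")
  if (n_lv > min(nrow(X) - 1, ncol(X)) || n_lv > qr(X)$rank)
    stop("plsda_fit: n_lv (", n_lv, ") exceeds rank(X)")

  n <- nrow(X); p <- ncol(X)
  W <- P <- matrix(0, p, n_lv)
  Tm <- matrix(0, n, n_lv)
  q <- ssy <- numeric(n_lv)
  Xa <- X
  ya <- y - mean(y)
  ssy_tot <- sum(ya^2)
  for (a in seq_len(n_lv)) {
    w <- crossprod(Xa, ya)
    nw <- sqrt(sum(w^2))
    if (nw <= 1e-14) stop("plsda_fit: residual X'y vanished at LV ", a)
    w <- w / nw
    t_ <- Xa %*% w
    tt <- sum(t_^2)
    p_ <- crossprod(Xa, t_) / tt
    q[a] <- sum(ya * t_) / tt
    Xa <- Xa - tcrossprod(t_, p_)
    ya <- ya - q[a] * t_
    W[, a] <- w; P[, a] <- p_; Tm[, a] <- t_
    ssy[a] <- q[a]^2 * tt
  }
  B <- W %*% solve(crossprod(P, W), q)
  rownames(W) <- rownames(P) <- colnames(X)
  structure(list(weights = W, x_loadings = P, scores = Tm, y_loadings = q,
                 coefficients = drop(B), ssy = ssy, ssy_total = ssy_tot,
                 y_mean = mean(y), n_lv = n_lv,
                 y_coding = y_coding,
                 feature_ids = colnames(X)),
            class = "plsda_model")
}

# Internal: map labels to the numeric class coding (default control = +1,
# treated = -1).
code_response <- function(y, y_coding = c(control = 1, treated = -1)) {
  if (is.numeric(y)) {
    if (!all(y %in% c(-1, 1))) stop("numeric y must be +1/-1")
    return(as.numeric(y))
  }
  y <- as.character(y)
  if (!all(y %in% names(y_coding)))
    stop("y labels must be ", paste(names(y_coding), collapse = "/"),
         " (or numeric +1/-1)")
  unname(y_coding[y])
}

#' Predict class membership from a fitted PLS-DA model
#'
#' The predicted response is `X_new %*% b` (plus the training response mean)
#' and the class is its sign: positive = control, negative = treated. An
#' exact zero is broken deterministically to control, with a warning.
#'
#' @param model A `plsda_model`.
#' @param X_new New samples scaled with the model's training scaling record.
#' @return Character vector of predicted labels with the numeric prediction
#'   in attribute `"y_hat"`.
#' @export
plsda_predict <- function(model, X_new) {
  X_new <- as.matrix(X_new)
  if (ncol(X_new) != length(model$coefficients))
    stop("plsda_predict: feature mismatch (", ncol(X_new), " vs ",
         length(model$coefficients), ")")
  y_hat <- drop(X_new %*% model$coefficients) + model$y_mean
  pos <- names(model$y_coding)[model$y_coding > 0]
  neg <- names(model$y_coding)[model$y_coding < 0]
  if (any(y_hat == 0))
    warning("plsda_predict: tie y_hat == 0 broken to '", pos, "'")
  labels <- ifelse(y_hat >= 0, pos, neg)
  attr(labels, "y_hat") <- y_hat
  labels
}

#' @export
predict.plsda_model <- function(object, newdata, ...) {
  plsda_predict(object, newdata)
}

#' Variable importance in projection (VIP)
#'
#' VIP_j = sqrt( p * sum_a [ SSY_a * w_ja^2 ] / sum_a SSY_a ), with
#' unit-norm weight vectors and SSY_a the Y-variance explained by LV a. The
#' squared VIPs always average to 1 (sum to the feature count).
#'
#' @param model A fitted `plsda_model`.
#' @return Named numeric vector of VIP scores.
#' @export
vip <- function(model) {
  if (sum(model$ssy) <= 1e-14)
    stop("vip: model explains no Y-variance")
  p <- nrow(model$weights)
  w2 <- model$weights^2  # columns already unit norm
  v <- sqrt(p * drop(w2 %*% model$ssy) / sum(model$ssy))
  stats::setNames(v, model$feature_ids)
}

#' Venetian-blind cross-validation over paired deletion groups
#'
#' Folds are the day-pairs: each deletion group removes the control and the
#' treated sample of one sampling day simultaneously (for a 6-day analysis
#' set this is 6 deletion groups, equivalently leave-one-pair-out). Day d is
#' assigned to fold ((d - 1) mod n_folds) + 1.
#'
#' Preprocessing is fold-safe: the input is expected pair-centered (which
#' uses no class labels and is computed within each pair, so held-out pairs
#' are centered by their own pair mean), while autoscaling parameters are
#' re-estimated on the training samples of each fold only.
#'
#' @param X Pair-centered (NOT autoscaled) samples x features matrix.
#' @param y Class labels (see [plsda_fit()]).
#' @param day Integer day of each sample, defining the pairs.
#' @param max_lv Largest LV count to evaluate (capped at the training rank).
#' @param n_folds Number of deletion groups; defaults to the number of days.
#' @param autoscale_in_fold Re-estimate scaling per fold (default TRUE); if
#'   FALSE, a single global autoscaling is used (for comparison only — it
#'   leaks distributional information across folds).
#' @return A `cv_result`: `folds` (held-out sample ids per fold),
#'   `error_by_nlv` (classification error rate), `rmse_by_nlv` (root mean
#'   squared error of the out-of-fold continuous prediction against the
#'   coded response), `best_n_lv` (argmin classification error, ties to the
#'   smallest LV count), `accuracy_cv` (percent, at `best_n_lv`),
#'   `predicted` (out-of-fold labels at `best_n_lv`).
#' @export
venetian_blind_cv <- function(X, y, day, max_lv = 5, n_folds = NULL,
                              autoscale_in_fold = TRUE) {
  X <- as.matrix(X)
  y <- code_response(y)
  if (max_lv < 1) stop("max_lv must be >= 1")
  days <- sort(unique(day))
  if (is.null(n_folds)) n_folds <- length(days)
  fold_of_day <- stats::setNames(((seq_along(days) - 1) %% n_folds) + 1, days)
  fold <- fold_of_day[as.character(day)]
  for (f in seq_len(n_folds)) {
    held_days <- unique(day[fold == f])
    if (any(!vapply(held_days, function(d) sum(day == d) == 2 &&
                      sum(y[day == d]) == 0, logical(1))))
      stop("design error: fold ", f, " does not hold out complete pairs")
  }

  if (!autoscale_in_fold) global_sc <- autoscale(X)
  err_counts <- sse <- numeric(max_lv)
  evaluated <- rep(TRUE, max_lv)
  pred <- matrix(NA_real_, nrow(X), max_lv)
  for (f in seq_len(n_folds)) {
    test <- which(fold == f)
    train <- which(fold != f)
    if (autoscale_in_fold) {
      sc <- suppressWarnings(autoscale(X[train, , drop = FALSE]))
      Xtr <- sc$matrix
      Xte <- apply_scaling(X[test, , drop = FALSE], sc$scaling_record)
    } else {
      Xtr <- global_sc$matrix[train, , drop = FALSE]
      Xte <- global_sc$matrix[test, , drop = FALSE]
    }
    y_hat <- pls_cv_predict(Xtr, y[train], Xte, max_lv)
    for (a in seq_len(max_lv)) {
      if (anyNA(y_hat[, a])) { evaluated[a] <- FALSE; next }
      pred_lab <- ifelse(y_hat[, a] >= 0, 1, -1)  # ties to control (+1)
      err_counts[a] <- err_counts[a] + sum(pred_lab != y[test])
      sse[a] <- sse[a] + sum((y_hat[, a] - y[test])^2)
      pred[test, a] <- y_hat[, a]
    }
  }
  err <- ifelse(evaluated, err_counts / nrow(X), NA_real_)
  rmse <- ifelse(evaluated, sqrt(sse / nrow(X)), NA_real_)
  best <- which(err == min(err, na.rm = TRUE))[1]  # ties: fewest LVs
  predicted <- ifelse(pred[, best] >= 0, "control", "treated")
  structure(list(folds = split(rownames(X) %||% seq_len(nrow(X)), fold),
                 error_by_nlv = err, rmse_by_nlv = rmse, best_n_lv = best,
                 accuracy_cv = 100 * (1 - err[best]),
                 predicted = predicted),
            class = "cv_result")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# Internal: one NIPALS pass on the training fold, returning the test-fold
# predicted responses for every LV count 1..max_lv (columns left NA when
# the training rank is exhausted before max_lv).
pls_cv_predict <- function(Xtr, ytr, Xte, max_lv) {
  p <- ncol(Xtr)
  W <- P <- matrix(0, p, max_lv)
  q <- numeric(max_lv)
  Xa <- Xtr
  y_mean <- mean(ytr)
  ya <- ytr - y_mean
  y_hat <- matrix(NA_real_, nrow(Xte), max_lv)
  for (a in seq_len(max_lv)) {
    w <- crossprod(Xa, ya)
    nw <- sqrt(sum(w^2))
    if (nw <= 1e-12) break
    w <- w / nw
    t_ <- Xa %*% w
    tt <- sum(t_^2)
    if (tt <= 1e-12) break
    p_ <- crossprod(Xa, t_) / tt
    q[a] <- sum(ya * t_) / tt
    Xa <- Xa - tcrossprod(t_, p_)
    ya <- ya - q[a] * t_
    W[, a] <- w
    P[, a] <- p_
    Wa <- W[, seq_len(a), drop = FALSE]
    B <- Wa %*% solve(crossprod(P[, seq_len(a), drop = FALSE], Wa),
                      q[seq_len(a)])
    y_hat[, a] <- Xte %*% B + y_mean
  }
  y_hat
}
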