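#' Backward-elimination PLS-DA (BE-PLS-DA)
#'
#' Iterative variable selection wrapped around two-class PLS-DA: at each
#' cycle the model is cross-validated (venetian blinds over paired deletion
#' groups) to choose the number of latent variables, the VIP scores of the
#' full-data fit at that LV count are computed, and the feature(s) with the
#' minimum VIP are removed. The retained set with the best (lowest)
#' cross-validated prediction error over the whole trace is selected and
#' the final model is refit on it. Prediction error is judged first by the
#' cross-validated classification error; because that error is coarse (it
#' can sit at zero over long stretches of the trace when the classes are
#' well separated), cycles with equal classification error are ranked by
#' the continuous cross-validated RMSE of the predicted response, which
#' keeps informative variables in and pushes pure-noise variables out;
#' remaining exact ties go to fewer features.
#'
#' All tie-breaks are deterministic: equal VIPs remove the lexicographically
#' smallest feature id; equal errors across LV counts prefer fewer LVs.
#'
#' By default one feature is removed per cycle, which makes the trace
#' minimum exact. For very wide matrices `remove_frac` removes the bottom
#' fraction of features per cycle while more than `min_exact` remain, then
#' reverts to one-at-a-time; results can differ slightly from the
#' one-at-a-time trace.
#'
#' @param X Pair-centered (NOT autoscaled) samples x features matrix, or a
#'   `fused_dataset` holding one. Autoscaling happens inside, fold-safely
#'   for CV and on all samples for the full-data fits.
#' @param y Class labels (control/treated).
#' @param day Integer day per sample defining the paired deletion groups
#'   (taken from `design`/pairing when `X` is a `fused_dataset` created with
#'   a design and `day` is missing).
#' @param max_lv Largest LV count considered (default 5).
#' @param remove_frac Fraction of current features removed per cycle while
#'   more than `min_exact` features remain; 0 (default) removes exactly one.
#' @param min_exact Feature count below which elimination is one-at-a-time.
#' @param block_index Optional named map feature id -> block for provenance
#'   in reports (taken from a `fused_dataset` automatically).
#' @param y_coding Class coding passed to [plsda_fit()].
#' @return A `beplsda_model`: `selected_features`, `model` (final
#'   `plsda_model`), `trace` (data frame: `n_features`, `cv_error`,
#'   `cv_rmse`, `n_lv`, `removed`, `removed_vip`), `accuracy_cal`,
#'   `accuracy_cv`, `n_lv`, `block_index`, `selected_by_block`.
#' @export
be_plsda <- function(X, y, day = NULL, max_lv = 5, remove_frac = 0,
                     min_exact = 50, block_index = NULL,
                     y_coding = c(control = 1, treated = -1)) {
  if (inherits(X, "fused_dataset")) {
    if (is.null(block_index)) block_index <- X$block_index
    if (is.null(day) && !is.null(X$pairing)) {
      day_of <- rep(as.integer(names(X$pairing)),
                    lengths(X$pairing))
      names(day_of) <- unlist(X$pairing, use.names = FALSE)
      day <- unname(day_of[X$sample_ids])
    }
    X <- X$matrix
  }
  X <- as.matrix(X)
  if (is.null(day)) stop("be_plsda: day pairing required")
  if (ncol(X) < 2) stop("be_plsda: need >= 2 features")
  if (is.null(colnames(X))) colnames(X) <- sprintf("f%05d", seq_len(ncol(X)))
  ycoded <- code_response(y, y_coding)

  features <- colnames(X)
  removed_per_cycle <- list()
  trace <- list()
  cycle <- 0L
  repeat {
    cycle <- cycle + 1L
    p <- length(features)
    Xc <- X[, features, drop = FALSE]
    cv <- venetian_blind_cv(Xc, ycoded, day, max_lv = max_lv)
    a <- cv$best_n_lv

    trace_row <- data.frame(n_features = p,
                            cv_error = cv$error_by_nlv[a],
                            cv_rmse = cv$rmse_by_nlv[a],
                            n_lv = a, removed = NA_character_,
                            removed_vip = NA_real_,
                            stringsAsFactors = FALSE)
    if (p == 1) {
      trace[[cycle]] <- trace_row
      removed_per_cycle[[cycle]] <- character(0)
      break
    }
    sc <- suppressWarnings(autoscale(Xc))
    full <- plsda_fit(sc$matrix, ycoded,
                      n_lv = min(a, qr(sc$matrix)$rank))
    v <- vip(full)
    if (any(!is.finite(v)))
      stop("be_plsda: non-finite VIP for feature(s) ",
           paste(names(v)[!is.finite(v)], collapse = ", "))
    # features dropped as constant during autoscaling are maximally
    # uninformative: eliminate them first
    dropped <- setdiff(features, names(v))
    n_remove <- if (remove_frac > 0 && p > min_exact)
      max(1L, min(floor(remove_frac * p), p - min_exact)) else 1L
    ord <- order(v, names(v))  # min VIP first, lexicographic tie-break
    remove <- c(dropped, names(v)[ord])[seq_len(min(n_remove, p - 1L))]
    trace_row$removed <- paste(remove, collapse = ";")
    trace_row$removed_vip <- if (remove[1] %in% names(v))
      unname(v[remove[1]]) else NA_real_
    trace[[cycle]] <- trace_row
    removed_per_cycle[[cycle]] <- remove
    features <- setdiff(features, remove)
  }
  trace <- do.call(rbind, trace)

  # best cycle: min CV classification error; ties by continuous CV RMSE;
  # remaining ties toward fewer features
  best_cycle <- order(trace$cv_error, trace$cv_rmse, trace$n_features)[1]
  selected <- colnames(X)
  if (best_cycle > 1)
    selected <- setdiff(selected,
                        unlist(removed_per_cycle[seq_len(best_cycle - 1L)]))

  # final refit on the selected set
  Xs <- X[, selected, drop = FALSE]
  cv_final <- venetian_blind_cv(Xs, ycoded, day, max_lv = max_lv)
  sc <- autoscale(Xs)
  n_lv_final <- min(trace$n_lv[best_cycle], qr(sc$matrix)$rank)
  final <- plsda_fit(sc$matrix, ycoded, n_lv = n_lv_final,
                     y_coding = y_coding)
  final$scaling_record <- sc$scaling_record
  cal_pred <- plsda_predict(final, sc$matrix)
  acc_cal <- 100 * mean(code_response(cal_pred, y_coding) == ycoded)

  sel_block <- if (!is.null(block_index)) block_index[selected] else NULL
  structure(list(selected_features = selected, model = final, trace = trace,
                 accuracy_cal = acc_cal,
                 accuracy_cv = 100 * (1 - trace$cv_error[best_cycle]),
                 n_lv = n_lv_final,
                 block_index = block_index,
                 selected_by_block = if (!is.null(sel_block))
                   table(factor(sel_block, levels = unique(block_index)))
                 else NULL),
            class = "beplsda_model")
}

#' BE-PLS-DA on a single omics source
#'
#' Runs the backward-elimination procedure on one block alone (pair-centering
#' it first), for comparison of single-source models against the fused
#' model.
#'
#' @param block An [omics_block()].
#' @param design Design rows for the analysis set.
#' @param ... Passed to [be_plsda()].
#' @return A `beplsda_model`.
#' @export
single_source_be <- function(block, design, ...) {
  if (length(block$feature_ids) < 1) stop("single_source_be: empty block")
  centered <- pair_center(block, design)
  d <- design[match(centered$sample_ids, design$sample_id), , drop = FALSE]
  bi <- stats::setNames(rep(block$block_name, length(block$feature_ids)),
                        block$feature_ids)
  be_plsda(centered$matrix, d$group, day = d$day, block_index = bi, ...)
}

#' Signed-coefficient report of a selected model
#'
#' One row per selected feature with its block, regression coefficient, VIP
#' and sign interpretation: a feature whose coefficient pushes predictions
#' toward the treated class ("increase") rises after treatment, one pushing
#' toward control ("decrease") falls. The interpretation is invariant to the
#' numeric class coding.
#'
#' @param fit A `beplsda_model`.
#' @return Data frame sorted by block then |coefficient| descending with
#'   columns `feature_id`, `block`, `coefficient`, `vip`, `interpretation`.
#' @export
coefficient_report <- function(fit) {
  stopifnot(inherits(fit, "beplsda_model"))
  b <- fit$model$coefficients
  v <- vip(fit$model)
  treated_code <- fit$model$y_coding[["treated"]]
  out <- data.frame(feature_id = fit$model$feature_ids,
                    block = if (!is.null(fit$block_index))
                      unname(fit$block_index[fit$model$feature_ids])
                    else NA_character_,
                    coefficient = unname(b),
                    vip = unname(v[fit$model$feature_ids]),
                    interpretation = ifelse(sign(b) == sign(treated_code),
                                            "increase", "decrease"),
                    stringsAsFactors = FALSE)
  out <- out[order(out$block, -abs(out$coefficient)), ]
  rownames(out) <- NULL
  out
}

#' @export
print.beplsda_model <- function(x, ...) {
  cat("BE-PLS-DA model:", length(x$selected_features), "selected features,",
      x$n_lv, "LV(s)\n")
  if (!is.null(x$selected_by_block)) {
    cat("Selected per block:",
        paste(names(x$selected_by_block), as.integer(x$selected_by_block),
              sep = "=", collapse = ", "), "\n")
  }
  cat(sprintf("Accuracy: %.1f%% calibration, %.1f%% cross-validation\n",
              x$accuracy_cal, x$accuracy_cv))
  invisible(x)
}
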