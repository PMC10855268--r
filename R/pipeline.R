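#' Configuration for a full pipeline run
#'
#' Collects every stage's parameters, with defaults mirroring the study
#' design the package emulates: 6 day-pairs per exposure time; per-site
#' omics sources muscle = lipidomics + metabolomics + proteomics
#' (921/464/66 features), skin = 944/384/99, gills = metabolomics +
#' proteomics (380/108), eye = metabolomics only (340); 16S community
#' profiling on skin, gills and eye.
#'
#' @param n_days_per_time Day-pairs per exposure time.
#' @param site_blocks Named list site -> named vector of block sizes.
#' @param microbiome_sites Sites with OTU tables.
#' @param n_planted,effect_size,day_effect_sd,noise_sd Synthetic-data
#'   parameters (see [synthetic_spec()]).
#' @param n_taxa,otu_dispersion,planted_log2fc OTU generator parameters; the
#'   planted log2 fold changes are applied to the first `length(planted_log2fc)`
#'   taxa.
#' @param mean_abundances Expected per-taxon counts at the nominal depth;
#'   defaults to the skewed [abundance_profile()].
#' @param n_dims MFA dimensions.
#' @param max_lv,remove_frac,min_exact BE-PLS-DA parameters.
#' @param n_perm PERMANOVA permutations.
#' @param rarefy_depth Rarefaction depth before diversity (NULL disables).
#' @param seed Master seed; every stage seed is derived from it as
#'   `(seed + offset) mod 2^31 - 1` with fixed stage offsets (omics site i:
#'   i; OTU table: 1000; microbiome permutations/rarefaction: 2000).
#' @return A `run_config` list.
#' @export
run_config <- function(n_days_per_time = 6,
                       site_blocks = list(
                         muscle = c(lipidomics = 921, metabolomics = 464,
                                    proteomics = 66),
                         skin = c(lipidomics = 944, metabolomics = 384,
                                  proteomics = 99),
                         gills = c(metabolomics = 380, proteomics = 108),
                         eye = c(metabolomics = 340)),
                       microbiome_sites = c("skin", "gills", "eye"),
                       n_planted = 10, effect_size = 3, day_effect_sd = 1,
                       noise_sd = 1, n_taxa = 50, otu_dispersion = 0.1,
                       mean_abundances = NULL,
                       planted_log2fc = c(2, 2, -2),
                       n_dims = 5, max_lv = 5, remove_frac = 0.2,
                       min_exact = 50, n_perm = 199, rarefy_depth = NULL,
                       seed = 1L) {
  cfg <- as.list(environment())
  if (length(cfg$site_blocks) == 0) stop("run_config: no sites configured")
  class(cfg) <- "run_config"
  cfg
}

stage_seed <- function(seed, offset) {
  as.integer((as.numeric(seed) + offset) %% (2^31 - 1))
}

#' Validate pipeline inputs
#'
#' Checks the design pairing, block/sample alignment, absence of missing
#' intensities, and count integrality/non-negativity. Returns a character
#' vector of problems; empty when everything is consistent.
#'
#' @param design Design data frame.
#' @param blocks Optional named list of [omics_block()]s.
#' @param otu Optional `otu_table` or count matrix.
#' @return Character vector of problem descriptions (length 0 if clean).
#' @export
validate_inputs <- function(design, blocks = NULL, otu = NULL) {
  problems <- character(0)
  if (anyDuplicated(design$sample_id))
    problems <- c(problems, "duplicate sample_id in design")
  for (st in unique(design$site)) {
    d <- design[design$site == st, , drop = FALSE]
    ok <- tryCatch({ check_pairing(d); TRUE },
                   error = function(e) conditionMessage(e))
    if (!isTRUE(ok)) problems <- c(problems, paste0("site ", st, ": ", ok))
  }
  for (b in blocks) {
    missing <- setdiff(b$sample_ids, design$sample_id)
    if (length(missing))
      problems <- c(problems, paste0("block ", b$block_name,
                                     ": samples not in design: ",
                                     paste(missing, collapse = ", ")))
    if (anyNA(b$matrix)) {
      bad <- which(is.na(b$matrix), arr.ind = TRUE)[1, ]
      problems <- c(problems, paste0("block ", b$block_name, ": NaN at sample ",
                                     b$sample_ids[bad[1]], ", feature ",
                                     b$feature_ids[bad[2]]))
    }
  }
  if (!is.null(otu)) {
    cts <- otu_counts(otu)
    if (any(cts < 0) || any(cts != round(cts)))
      problems <- c(problems, "OTU counts must be non-negative integers")
    missing <- setdiff(colnames(cts), design$sample_id)
    if (length(missing))
      problems <- c(problems, paste0("OTU samples not in design: ",
                                     paste(missing, collapse = ", ")))
  }
  problems
}

#' Run the full analysis pipeline on synthetic data
#'
#' Orchestrates, deterministically under the configured seed: synthetic data
#' generation per site, day-pair centering + autoscaling, MFA per site (all
#' four classes jointly, class variable active), BE-PLS-DA per (site, time)
#' for the fused sources and each single source, and the microbiome
#' statistics chain on the configured sites.
#'
#' @param config A [run_config()].
#' @return A list of class `run_summary`: `summary` (one row per fitted
#'   discriminant model: site, time, sources with original and selected
#'   variable counts, n_lv, calibration and CV accuracy), `mfa` (per-site
#'   `mfa_result`s), `beplsda` (nested site -> time -> model list),
#'   `microbiome` (output of [run_comparisons()]), `design`, `truth`.
#' @export
run_all <- function(config = run_config()) {
  stopifnot(inherits(config, "run_config"))
  sites <- names(config$site_blocks)
  design <- generate_design(config$n_days_per_time, sites)

  mfa_res <- list(); be_res <- list(); truth <- list()
  summary_rows <- list()
  for (i in seq_along(sites)) {
    st <- sites[i]
    dsite <- design[design$site == st, , drop = FALSE]
    spec <- synthetic_spec(block_sizes = config$site_blocks[[st]],
                           n_planted = config$n_planted,
                           effect_size = config$effect_size,
                           day_effect_sd = config$day_effect_sd,
                           noise_sd = config$noise_sd,
                           seed = stage_seed(config$seed, i))
    sim <- generate_multiomics(dsite, spec)
    truth[[st]] <- sim$truth

    # MFA over the whole site (both times): pair-center, autoscale per
    # feature, weight blocks, include the 4-level class variable
    centered <- lapply(sim$blocks, pair_center, design = dsite)
    scaled <- lapply(centered, function(b) autoscale(b$matrix)$matrix)
    classes <- paste(dsite$time,
                     dsite$group)[match(rownames(scaled[[1]]),
                                        dsite$sample_id)]
    mfa_res[[st]] <- mfa_fit(scaled, classes = classes,
                             n_dims = config$n_dims)

    be_res[[st]] <- list()
    for (tm in c("t3h", "t24h")) {
      dsub <- dsite[dsite$time == tm, , drop = FALSE]
      blocks_sub <- lapply(sim$blocks, function(b) {
        keep <- b$sample_ids %in% dsub$sample_id
        omics_block(b$block_name, b$matrix[keep, , drop = FALSE])
      })
      centered_sub <- lapply(blocks_sub, pair_center, design = dsub)
      fused <- fuse(centered_sub, dsub)
      yd <- dsub[match(fused$sample_ids, dsub$sample_id), , drop = FALSE]
      global <- be_plsda(fused, yd$group, max_lv = config$max_lv,
                         remove_frac = config$remove_frac,
                         min_exact = config$min_exact)
      singles <- lapply(blocks_sub, single_source_be, design = dsub,
                        max_lv = config$max_lv,
                        remove_frac = config$remove_frac,
                        min_exact = config$min_exact)
      be_res[[st]][[tm]] <- c(list(global = global), singles)

      fmt_src <- function(counts)
        paste(sprintf("%s (%d)", names(counts), as.integer(counts)),
              collapse = " + ")
      orig <- vapply(sim$blocks, function(b) length(b$feature_ids), 1L)
      summary_rows[[length(summary_rows) + 1L]] <- data.frame(
        site = st, time = tm, model = "global",
        sources_original = fmt_src(orig),
        sources_selected = fmt_src(global$selected_by_block),
        n_lv = global$n_lv, acc_cal = global$accuracy_cal,
        acc_cv = global$accuracy_cv, stringsAsFactors = FALSE)
      for (b in names(singles)) {
        summary_rows[[length(summary_rows) + 1L]] <- data.frame(
          site = st, time = tm, model = b,
          sources_original = fmt_src(orig[b]),
          sources_selected = fmt_src(singles[[b]]$selected_by_block),
          n_lv = singles[[b]]$n_lv, acc_cal = singles[[b]]$accuracy_cal,
          acc_cv = singles[[b]]$accuracy_cv, stringsAsFactors = FALSE)
      }
    }
  }

  microbiome <- NULL
  mb_sites <- intersect(config$microbiome_sites, sites)
  if (length(mb_sites)) {
    dmb <- design[design$site %in% mb_sites, , drop = FALSE]
    l2fc <- stats::setNames(config$planted_log2fc,
                            seq_along(config$planted_log2fc))
    ab <- config$mean_abundances
    if (is.null(ab)) ab <- abundance_profile(config$n_taxa)
    sim_otu <- generate_otu_counts(dmb, n_taxa = config$n_taxa,
                                   mean_abundances = ab,
                                   dispersion = config$otu_dispersion,
                                   planted_log2fc = l2fc,
                                   seed = stage_seed(config$seed, 1000))
    microbiome <- run_comparisons(sim_otu$otu, dmb, n_perm = config$n_perm,
                                  seed = stage_seed(config$seed, 2000),
                                  rarefy_depth = config$rarefy_depth)
    microbiome$truth <- sim_otu$truth
  }

  structure(list(summary = do.call(rbind, summary_rows), mfa = mfa_res,
                 beplsda = be_res, microbiome = microbiome,
                 design = design, truth = truth, config = config),
            class = "run_summary")
}

#' @export
print.run_summary <- function(x, ...) {
  cat("Pipeline run:", length(x$mfa), "site(s),",
      nrow(x$summary), "discriminant model(s)\n\n")
  print(x$summary, row.names = FALSE)
  invisible(x)
}
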