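#!/usr/bin/env Rscript
# Stage 2 — Multiple Factor Analysis per sampling site.
#
# For each site, the simulated blocks are day-pair centered, autoscaled and
# combined by MFA with each block weighted by the inverse of its first PCA
# eigenvalue; the four-level class variable (time x treatment) enters as an
# active qualitative block. Writes scores, eigenvalues/variance explained,
# and block/variable contribution tables under results/mfa/.

suppressPackageStartupMessages(library(fusedomics))

design <- read_design_tsv("results/sim/design.tsv")
sites <- unique(design$site)
out <- "results/mfa"

for (st in sites) {
  dsite <- design[design$site == st, ]
  files <- list.files(file.path("results/sim", st),
                      pattern = "^block_.*\\.tsv$", full.names = TRUE)
  blocks <- lapply(files, read_block_tsv)
  names(blocks) <- vapply(blocks, function(b) b$block_name, "")

  scaled <- lapply(blocks, function(b)
    autoscale(pair_center(b, dsite)$matrix)$matrix)
  ids <- rownames(scaled[[1]])
  classes <- paste(dsite$time, dsite$group)[match(ids, dsite$sample_id)]
  res <- mfa_fit(scaled, classes = classes, n_dims = 5)

  k <- res$n_dims
  write_tsv_report(data.frame(sample_id = ids, class = classes,
                              res$scores, check.names = FALSE),
                   file.path(out, paste0(st, "_scores.tsv")))
  write_tsv_report(data.frame(dimension = seq_along(res$eigenvalues),
                              eigenvalue = res$eigenvalues,
                              variance_explained_pct =
                                res$variance_explained),
                   file.path(out, paste0(st, "_eigenvalues.tsv")))
  write_tsv_report(data.frame(block = rownames(res$block_contributions),
                              round(res$block_contributions, 3),
                              check.names = FALSE),
                   file.path(out, paste0(st, "_block_contributions.tsv")))
  vc <- res$variable_contributions
  vc <- vc[order(-vc[, 1]), , drop = FALSE]
  write_tsv_report(data.frame(feature_id = rownames(vc), round(vc, 4),
                              check.names = FALSE),
                   file.path(out, paste0(st, "_variable_contributions.tsv")))

  message(sprintf(
    "%s: dim1 %.1f%% + dim2 %.1f%% of variance; block contributions to dim1: %s",
    st, res$variance_explained[1], res$variance_explained[2],
    paste(rownames(res$block_contributions),
          sprintf("%.1f%%", res$block_contributions[, 1]),
          sep = " ", collapse = ", ")))
}
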