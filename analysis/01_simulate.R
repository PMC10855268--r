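#!/usr/bin/env Rscript
# Stage 1 — simulate the paired study design.
#
# Generates the full 24-fish / 12-day paired design (6 day-pairs per
# exposure time), per-site multi-omics blocks with the study's block widths
# (muscle 921/464/66, skin 944/384/99, gills 380/108, eye 340) carrying a
# sparse planted treatment effect, and an overdispersed family-level OTU
# table for the three community-profiled sites. Writes everything as TSV
# under results/sim/ together with the planted truth, so the later stages
# can be checked against known ground truth.

suppressPackageStartupMessages(library(fusedomics))

args <- commandArgs(trailingOnly = TRUE)
seed <- if (length(args) >= 2 && args[1] == "--seed") as.integer(args[2]) else 1L
cfg <- run_config(seed = seed)

design <- generate_design(cfg$n_days_per_time, names(cfg$site_blocks))
message(nrow(design), " samples: ", length(unique(design$fish_id)),
        " fish x ", length(cfg$site_blocks), " sites, ",
        length(unique(design$day)), " day-pairs")

out <- "results/sim"
dir.create(out, recursive = TRUE, showWarnings = FALSE)
write_tsv_report(design, file.path(out, "design.tsv"),
                 comment = paste("paired design, seed", seed))

for (i in seq_along(cfg$site_blocks)) {
  st <- names(cfg$site_blocks)[i]
  dsite <- design[design$site == st, ]
  spec <- synthetic_spec(block_sizes = cfg$site_blocks[[st]],
                         n_planted = cfg$n_planted,
                         effect_size = cfg$effect_size,
                         day_effect_sd = cfg$day_effect_sd,
                         noise_sd = cfg$noise_sd,
                         seed = (seed + i) %% (2^31 - 1))
  sim <- generate_multiomics(dsite, spec)
  site_dir <- file.path(out, st)
  write_synthetic_tsv(site_dir, dsite, sim$blocks, sim$truth)
  message(st, ": blocks ",
          paste(names(cfg$site_blocks[[st]]), cfg$site_blocks[[st]],
                sep = "=", collapse = ", "),
          "; ", nrow(sim$truth), " planted features")
}

dmb <- design[design$site %in% cfg$microbiome_sites, ]
ab <- cfg$mean_abundances
if (is.null(ab)) ab <- abundance_profile(cfg$n_taxa)
otu <- generate_otu_counts(dmb, n_taxa = cfg$n_taxa,
                           mean_abundances = ab,
                           dispersion = cfg$otu_dispersion,
                           planted_log2fc = stats::setNames(
                             cfg$planted_log2fc,
                             seq_along(cfg$planted_log2fc)),
                           seed = (seed + 1000) %% (2^31 - 1))
write_synthetic_tsv(file.path(out, "microbiome"), dmb,
                    otu = otu$otu, otu_truth = otu$truth)
message("OTU table: ", nrow(otu$otu$counts), " families x ",
        ncol(otu$otu$counts), " samples; planted fold changes on ",
        nrow(otu$truth), " taxa")
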