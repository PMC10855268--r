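#!/usr/bin/env Rscript
# Stage 4 — 16S community statistics.
#
# On the simulated family-level OTU table: alpha diversity (bias-corrected
# Chao1, Shannon, Gini-Simpson) with Kruskal-Wallis tests, Bray-Curtis
# dissimilarities with PCoA and PERMANOVA per site, and the six standard
# differential-abundance contrasts (TMM-normalized negative-binomial Wald
# tests, BH-FDR per contrast). Writes diversity, ordination and
# DAA tables under results/microbiome/.

suppressPackageStartupMessages(library(fusedomics))

design <- read_design_tsv("results/sim/microbiome/design.tsv")
otu <- read_otu_tsv("results/sim/microbiome/otu_counts.tsv")
out <- "results/microbiome"

res <- run_comparisons(otu, design, n_perm = 999, seed = 7,
                       rarefy_depth = NULL)

# community composition summary (top families, percent)
write_tsv_report(relative_abundance_table(otu, design, top = 10),
                 file.path(out, "relative_abundance.tsv"))

for (st in names(res$diversity)) {
  write_tsv_report(res$diversity[[st]]$alpha,
                   file.path(out, paste0(st, "_alpha_diversity.tsv")))
  co <- res$pcoa[[st]]$coordinates
  write_tsv_report(data.frame(sample_id = rownames(co), co),
                   file.path(out, paste0(st, "_pcoa.tsv")))
  message(sprintf(
    "%s: Kruskal-Wallis p (chao1/shannon/simpson) = %.3f/%.3f/%.3f; PERMANOVA F = %.2f, p = %.3f",
    st, res$diversity[[st]]$kruskal_wallis_p["chao1"],
    res$diversity[[st]]$kruskal_wallis_p["shannon"],
    res$diversity[[st]]$kruskal_wallis_p["simpson"],
    res$permanova[[st]]$pseudo_F, res$permanova[[st]]$p_value))
}

daa_all <- do.call(rbind, lapply(names(res$daa), function(nm) {
  r <- res$daa[[nm]]
  data.frame(contrast = nm, r)
}))
write_tsv_report(daa_all, file.path(out, "daa_all_contrasts.tsv"))

sig <- daa_all[daa_all$fdr_p < 0.05, ]
sig <- sig[order(sig$contrast, sig$fdr_p),
           c("contrast", "taxon", "max_group_mean", "log2_fold_change",
             "fold_change", "wald_p", "fdr_p")]
write_tsv_report(sig, file.path(out, "daa_significant.tsv"),
                 comment = "FDR < 0.05 per contrast (BH within contrast)")
message("\n", nrow(sig), " significant family-level results across ",
        length(res$daa), " contrasts -> ",
        file.path(out, "daa_significant.tsv"))
truth <- utils::read.delim("results/sim/microbiome/otu_truth.tsv")
message("planted taxa: ",
        paste(truth$taxon, sprintf("(log2FC %+.1f)", truth$log2fc),
              collapse = ", "))
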