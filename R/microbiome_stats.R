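#' Bias-corrected Chao1 richness estimate
#'
#' `S_obs + f1 (f1 - 1) / (2 (f2 + 1))`, with `f1`/`f2` the numbers of
#' singleton and doubleton taxa. Always at least the observed richness.
#'
#' @param counts Non-negative integer count vector for one sample.
#' @return The Chao1 (bias-corrected) estimate.
#' @export
chao1_bc <- function(counts) {
  counts <- check_counts(counts)
  if (sum(counts) == 0) stop("chao1_bc: empty sample")
  s_obs <- sum(counts > 0)
  f1 <- sum(counts == 1)
  f2 <- sum(counts == 2)
  s_obs + f1 * (f1 - 1) / (2 * (f2 + 1))
}

#' Shannon entropy of a sample
#'
#' `H = -sum p_i log p_i`; natural log by default, with `base = 2` for the
#' log2 convention. Bounded above by log of observed richness.
#'
#' @param counts Count (or abundance) vector.
#' @param base Logarithm base (default `exp(1)`).
#' @return Shannon entropy H.
#' @export
shannon <- function(counts, base = exp(1)) {
  counts <- check_counts(counts)
  if (sum(counts) == 0) stop("shannon: empty sample")
  unname(vegan::diversity(counts, index = "shannon", base = base))
}

#' Simpson's diversity index
#'
#' The Gini-Simpson form `1 - sum p_i^2` by default (the probability two
#' random reads belong to different taxa); `gini = FALSE` returns the raw
#' concentration `sum p_i^2`.
#'
#' @param counts Count (or abundance) vector.
#' @param gini Return `1 - sum p^2` (default) instead of `sum p^2`.
#' @return Simpson index.
#' @export
simpson <- function(counts, gini = TRUE) {
  counts <- check_counts(counts)
  if (sum(counts) == 0) stop("simpson: empty sample")
  d <- unname(vegan::diversity(counts, index = "simpson"))
  if (gini) d else 1 - d
}

check_counts <- function(counts) {
  counts <- as.numeric(counts)
  if (any(counts < 0)) stop("counts must be non-negative")
  counts
}

#' Bray-Curtis dissimilarity matrix
#'
#' `d(x, y) = sum |x_i - y_i| / sum (x_i + y_i)`; symmetric, zero diagonal,
#' in [0, 1] for non-negative input.
#'
#' @param x Samples x taxa abundance matrix.
#' @return A `dist` object.
#' @export
bray_curtis <- function(x) {
  x <- as.matrix(x)
  if (any(x < 0)) stop("bray_curtis: negative abundances")
  vegan::vegdist(x, method = "bray")
}

#' Principal coordinates analysis (PCoA)
#'
#' Classical metric scaling: Gower double-centering of -D^2/2 followed by
#' eigendecomposition; coordinates are eigenvectors scaled by the square
#' root of their (positive) eigenvalues. Negative eigenvalues, which arise
#' for non-Euclidean dissimilarities such as Bray-Curtis, are reported and
#' their axes dropped with a warning.
#'
#' @param d A `dist` object or symmetric distance matrix.
#' @param k Number of coordinate axes requested.
#' @return List with `coordinates` (samples x <= k), `eigenvalues` (all,
#'   sorted descending), `variance_explained` (percent of the positive
#'   eigenvalue total, per returned axis).
#' @export
pcoa <- function(d, k = 2) {
  d <- stats::as.dist(d)
  n <- attr(d, "Size")
  if (k > n - 1) k <- n - 1
  fit <- suppressWarnings(stats::cmdscale(d, k = k, eig = TRUE))
  eig <- sort(fit$eig, decreasing = TRUE)
  pos <- sum(eig > sqrt(.Machine$double.eps) * abs(eig[1]))
  if (pos < k)
    warning("pcoa: only ", pos, " positive eigenvalue(s); ",
            "negative-eigenvalue axes dropped")
  keep <- min(k, pos)
  coords <- fit$points[, seq_len(keep), drop = FALSE]
  colnames(coords) <- paste0("axis", seq_len(keep))
  list(coordinates = coords, eigenvalues = eig,
       variance_explained = 100 * eig[seq_len(keep)] / sum(eig[eig > 0]))
}

#' PERMANOVA on a distance matrix
#'
#' Permutational multivariate analysis of variance: the pseudo-F statistic
#' from among-/within-group sums of squared distances, with the p-value
#' `(1 + #{permuted F >= observed}) / (1 + n_perm)` from seeded permutations
#' of the group labels.
#'
#' @param d `dist` object or distance matrix.
#' @param groups Group label per sample.
#' @param n_perm Number of permutations (default 999).
#' @param seed Integer seed for the permutations.
#' @return List with `pseudo_F`, `p_value`, `df` and the underlying
#'   `vegan::adonis2` table.
#' @export
permanova <- function(d, groups, n_perm = 999, seed = 1L) {
  d <- stats::as.dist(d)
  groups <- as.factor(groups)
  tab <- withr::with_seed(seed,
    vegan::adonis2(d ~ groups, permutations = n_perm))
  list(pseudo_F = tab$F[1], p_value = tab$`Pr(>F)`[1],
       df = c(among = tab$Df[1], within = tab$Df[2]), table = tab)
}

#' Kruskal-Wallis rank test
#'
#' Tie-corrected rank-based H statistic with a chi-square p-value on
#' (groups - 1) degrees of freedom; used for group comparisons of alpha
#' diversity indices.
#'
#' @param values Numeric vector (e.g. per-sample diversity values).
#' @param groups Group label per value.
#' @return List with `H` and `p_value`. When every value is identical the
#'   tie correction degenerates (0/0); by convention H = 0 and p = 1 (no
#'   evidence of any group difference).
#' @export
kruskal_wallis <- function(values, groups) {
  if (length(unique(values)) == 1)
    return(list(H = 0, p_value = 1))
  fit <- stats::kruskal.test(values, as.factor(groups))
  list(H = unname(fit$statistic), p_value = fit$p.value)
}

#' TMM normalization factors
#'
#' Trimmed mean of M-values: per sample, a weighted mean of taxon-wise log2
#' ratios against a reference sample after two-sided trimming of 30% of the
#' M-values (log ratios) and 5% of the A-values (log abundances), with
#' inverse asymptotic-variance weights; factors are renormalized to have
#' geometric mean 1. The default reference is the sample whose upper
#' quartile is closest to the mean upper quartile. Taxa with a zero count in
#' either member of a pair are excluded from that pair's trimmed mean.
#'
#' @param counts Taxa x samples count matrix (or `otu_table`).
#' @param reference Optional reference column (index or name).
#' @return Named per-sample normalization factors (geometric mean 1).
#' @export
tmm_factors <- function(counts, reference = NULL) {
  counts <- otu_counts(counts)
  if (any(colSums(counts) == 0))
    stop("tmm_factors: sample(s) with all-zero counts: ",
         paste(colnames(counts)[colSums(counts) == 0], collapse = ", "))
  ref <- if (is.null(reference)) NULL else
    if (is.character(reference)) match(reference, colnames(counts)) else reference
  f <- edgeR::calcNormFactors(counts, method = "TMM", refColumn = ref,
                              logratioTrim = 0.3, sumTrim = 0.05,
                              doWeighting = TRUE)
  stats::setNames(as.numeric(f), colnames(counts))
}

otu_counts <- function(x) {
  if (inherits(x, "otu_table")) x$counts else as.matrix(x)
}

#' Negative-binomial Wald test of differential abundance
#'
#' Per taxon, a negative-binomial GLM with log link and offset
#' `log(library_size x TMM factor)` is fit by maximum likelihood (per-taxon
#' dispersion, no shrinkage), and the Wald statistic `z = beta / SE` of the
#' group coefficient gives a two-sided normal p-value. The natural-log group
#' coefficient is converted to a log2 fold change and p-values are
#' Benjamini-Hochberg adjusted across the taxa of this one comparison. Taxa
#' with zero counts in both groups are excluded (with a message).
#'
#' @param counts Taxa x samples count matrix (or `otu_table`) restricted to
#'   the two groups under comparison.
#' @param groups Two-level factor/character per sample; the fold change is
#'   second level vs first (reference) level.
#' @param factors TMM factors from [tmm_factors()] (computed if missing).
#' @param lib_size Per-sample library sizes (column sums if missing).
#' @return Data frame of class `daa_result`: `taxon`, `max_group_mean`
#'   (larger group mean of normalized counts), `log2_fold_change`,
#'   `fold_change` (2^log2FC at 2 significant figures), `wald_p`, `fdr_p`.
#' @export
daa_wald <- function(counts, groups, factors = NULL, lib_size = NULL) {
  counts <- otu_counts(counts)
  groups <- as.factor(as.character(groups))
  if (nlevels(groups) != 2)
    stop("daa_wald: exactly two groups required")
  if (is.null(lib_size)) lib_size <- colSums(counts)
  if (is.null(factors)) factors <- tmm_factors(counts)
  eff_lib <- lib_size * factors
  offset <- log(eff_lib)

  all_zero <- rowSums(counts) == 0
  if (any(all_zero))
    message("daa_wald: excluding ", sum(all_zero),
            " taxa with zero counts in both groups")
  keep <- which(!all_zero)

  norm_counts <- sweep(counts, 2, eff_lib / mean(lib_size), "/")
  res <- lapply(keep, function(i) {
    y <- counts[i, ]
    fit <- tryCatch(
      suppressWarnings(MASS::glm.nb(y ~ groups + offset(offset))),
      error = function(e) NULL)
    if (is.null(fit) || !fit$converged)
      fit <- suppressWarnings(
        stats::glm(y ~ groups + offset(offset), family = stats::poisson()))
    sm <- summary(fit)$coefficients
    beta <- sm[2, 1]; se <- sm[2, 2]
    gm <- tapply(norm_counts[i, ], groups, mean)
    data.frame(taxon = rownames(counts)[i],
               max_group_mean = max(gm),
               log2_fold_change = beta / log(2),
               wald_p = 2 * stats::pnorm(-abs(beta / se)),
               stringsAsFactors = FALSE)
  })
  res <- do.call(rbind, res)
  res$fold_change <- fold_change(res$log2_fold_change)
  res$fdr_p <- stats::p.adjust(res$wald_p, method = "BH")
  res <- res[, c("taxon", "max_group_mean", "log2_fold_change",
                 "fold_change", "wald_p", "fdr_p")]
  rownames(res) <- NULL
  class(res) <- c("daa_result", "data.frame")
  res
}

#' Fold change from a log2 fold change
#'
#' `2^log2fc`, reported at 2 significant figures to match the usual style
#' of differential-abundance summary tables.
#'
#' @param log2fc Numeric log2 fold change(s).
#' @param digits Significant figures (default 2).
#' @return Fold change(s).
#' @export
fold_change <- function(log2fc, digits = 2) {
  signif(2^log2fc, digits)
}

#' Rarefy a count table to fixed depth
#'
#' Seeded subsampling of reads without replacement to a common depth;
#' samples below the depth are dropped with a warning. Applied before
#' diversity estimation (but not before differential abundance, where TMM
#' normalization handles depth).
#'
#' @param counts Taxa x samples count matrix (or `otu_table`).
#' @param depth Target depth (default 10000 reads).
#' @param seed Integer seed.
#' @return Rarefied count matrix.
#' @export
rarefy_counts <- function(counts, depth = 10000, seed = 1L) {
  counts <- otu_counts(counts)
  shallow <- colSums(counts) < depth
  if (any(shallow)) {
    warning("rarefy_counts: dropping ", sum(shallow),
            " sample(s) below depth ", depth)
    counts <- counts[, !shallow, drop = FALSE]
  }
  if (ncol(counts) == 0) stop("rarefy_counts: no samples at depth")
  withr::with_seed(seed, {
    out <- apply(counts, 2, function(x) {
      reads <- sample(rep.int(seq_along(x), x), depth)
      tabulate(reads, nbins = length(x))
    })
    rownames(out) <- rownames(counts)
    out
  })
}

#' Run the standard set of group comparisons on an OTU table
#'
#' Executes the six differential-abundance contrasts of the study design
#' for the sites present: per site, control vs treated at 3 h and at 24 h;
#' per site, 3 h vs 24 h within controls and within treated; and, pooling
#' all sites, control vs treated at 3 h and at 24 h. Each contrast gets its
#' own TMM factors and its own FDR family. Alpha diversity (Chao1,
#' Shannon, Gini-Simpson after rarefaction), Bray-Curtis PCoA and PERMANOVA
#' are computed per site on relative abundances.
#'
#' @param otu An `otu_table` (see [generate_otu_counts()]) or taxa x samples
#'   count matrix whose columns match `design$sample_id`.
#' @param design Design rows matching the OTU samples.
#' @param n_perm PERMANOVA permutations.
#' @param seed Integer seed (rarefaction, permutations).
#' @param rarefy_depth Depth for diversity rarefaction; `NULL` disables.
#' @return List with `daa` (named list of `daa_result`s, one per feasible
#'   contrast), `diversity` (per-sample alpha indices + Kruskal-Wallis
#'   p-values per site), `pcoa` (per-site coordinates), `permanova`
#'   (per-site results).
#' @export
run_comparisons <- function(otu, design, n_perm = 999, seed = 1L,
                            rarefy_depth = 10000) {
  counts <- otu_counts(otu)
  design <- design[match(colnames(counts), design$sample_id), , drop = FALSE]
  if (anyNA(design$sample_id))
    stop("run_comparisons: OTU samples missing from design")
  sites <- unique(design$site)

  contrast_sets <- list()
  for (s in sites) {
    for (tm in c("t3h", "t24h")) {
      sel <- design$site == s & design$time == tm
      contrast_sets[[paste(s, tm, "control_vs_treated", sep = ".")]] <-
        list(idx = which(sel), var = "group")
    }
    for (g in c("control", "treated")) {
      sel <- design$site == s & design$group == g
      contrast_sets[[paste(s, g, "t3h_vs_t24h", sep = ".")]] <-
        list(idx = which(sel), var = "time")
    }
  }
  for (tm in c("t3h", "t24h")) {
    sel <- design$time == tm
    contrast_sets[[paste("all_sites", tm, "control_vs_treated", sep = ".")]] <-
      list(idx = which(sel), var = "group")
  }

  daa <- list()
  for (nm in names(contrast_sets)) {
    cs <- contrast_sets[[nm]]
    g <- design[[cs$var]][cs$idx]
    if (length(unique(g)) < 2 || min(table(g)) < 2) {
      warning("run_comparisons: contrast '", nm, "' has <2 samples per ",
              "group, skipped")
      next
    }
    sub <- counts[, cs$idx, drop = FALSE]
    sub <- sub[rowSums(sub) > 0, , drop = FALSE]
    daa[[nm]] <- daa_wald(sub, g)
  }

  diversity <- list(); pcoa_res <- list(); perma <- list()
  for (s in sites) {
    idx <- which(design$site == s)
    sub <- counts[, idx, drop = FALSE]
    dsub <- design[idx, , drop = FALSE]
    div_counts <- if (!is.null(rarefy_depth))
      rarefy_counts(sub, depth = rarefy_depth, seed = seed) else sub
    kept <- colnames(div_counts)
    dk <- dsub[match(kept, dsub$sample_id), , drop = FALSE]
    alpha <- data.frame(sample_id = kept,
                        group = dk$group, time = dk$time,
                        chao1 = apply(div_counts, 2, chao1_bc),
                        shannon = apply(div_counts, 2, shannon),
                        simpson = apply(div_counts, 2, simpson),
                        stringsAsFactors = FALSE)
    kw <- lapply(c(chao1 = "chao1", shannon = "shannon", simpson = "simpson"),
                 function(v) kruskal_wallis(alpha[[v]],
                                            paste(dk$group, dk$time))$p_value)
    rel <- t(sweep(sub, 2, colSums(sub), "/"))
    d <- bray_curtis(rel)
    pcoa_res[[s]] <- pcoa(d, k = 2)
    perma[[s]] <- permanova(d, paste(dsub$group, dsub$time),
                            n_perm = n_perm, seed = seed)
    diversity[[s]] <- list(alpha = alpha, kruskal_wallis_p = unlist(kw))
  }
  list(daa = daa, diversity = diversity, pcoa = pcoa_res, permanova = perma)
}

#' Relative-abundance summary table
#'
#' Mean relative abundance (percent, 2 decimal places) per taxon within each
#' group x time, sorted descending — the usual community-composition summary
#' table.
#'
#' @param otu `otu_table` or count matrix.
#' @param design Matching design rows.
#' @param top Number of taxa reported per stratum.
#' @return Long data frame: `group`, `time`, `taxon`, `abundance_pct`.
#' @export
relative_abundance_table <- function(otu, design, top = 10) {
  counts <- otu_counts(otu)
  design <- design[match(colnames(counts), design$sample_id), , drop = FALSE]
  rel <- sweep(counts, 2, colSums(counts), "/") * 100
  strata <- split(seq_len(ncol(rel)), paste(design$group, design$time))
  out <- lapply(names(strata), function(nm) {
    m <- sort(rowMeans(rel[, strata[[nm]], drop = FALSE]), decreasing = TRUE)
    m <- utils::head(m, top)
    gp <- strsplit(nm, " ")[[1]]
    data.frame(group = gp[1], time = gp[2], taxon = names(m),
               abundance_pct = round(unname(m), 2), stringsAsFactors = FALSE)
  })
  do.call(rbind, out)
}
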