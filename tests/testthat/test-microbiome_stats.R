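test_that("alpha diversity indices match closed forms and known bounds", {
  # S_obs = 4, f1 = 2, f2 = 0: 4 + 2*1/(2*1) = 5
  expect_equal(chao1_bc(c(5, 3, 1, 1)), 5)
  expect_equal(chao1_bc(c(5, 3, 2, 2)), 4)  # no singletons -> S_obs
  expect_error(chao1_bc(c(0, 0)), "empty")

  expect_equal(shannon(rep(10, 4)), log(4))
  expect_equal(shannon(c(0, 50, 0)), 0)
  expect_equal(simpson(rep(10, 4)), 0.75)
  expect_equal(simpson(c(0, 50, 0)), 0)
  expect_equal(simpson(rep(10, 4), gini = FALSE), 0.25)

  set.seed(10)
  for (i in 1:10) {
    v <- rpois(30, 3)
    if (sum(v) == 0) next
    expect_gte(chao1_bc(v), sum(v > 0))
    expect_lte(shannon(v), log(sum(v > 0)) + 1e-12)
    # taxon-order invariance
    perm <- sample(30)
    expect_equal(chao1_bc(v[perm]), chao1_bc(v))
    expect_equal(shannon(v[perm]), shannon(v))
    expect_equal(simpson(v[perm]), simpson(v))
  }

  # cross-check the bias-corrected Chao1 against vegan's estimator
  set.seed(11)
  for (i in 1:5) {
    v <- rpois(40, 2)
    expect_equal(chao1_bc(v),
                 unname(vegan::estimateR(v)["S.chao1"]), tolerance = 1e-10)
  }
})

test_that("Bray-Curtis has its defining properties", {
  x <- rbind(a = c(2, 2), b = c(1, 1), c = c(0, 3))
  d <- as.matrix(bray_curtis(x))
  expect_equal(d["a", "b"], 1 / 3)
  expect_equal(d["a", "a"], 0)
  expect_equal(as.matrix(bray_curtis(rbind(c(1, 0), c(0, 5))))[1, 2], 1)
  # invariant to joint scaling of both samples
  expect_equal(as.matrix(bray_curtis(x * 7)), d)
  expect_true(all(d >= 0 & d <= 1))
  expect_equal(d, t(d))
})

test_that("PCoA reproduces Euclidean configurations (Gower theorem)", {
  set.seed(12)
  pts <- matrix(rnorm(10), 5, 2)
  d <- stats::dist(pts)
  fit <- pcoa(d, k = 2)
  expect_lt(max(abs(stats::dist(fit$coordinates) - d)), 1e-8)
  expect_true(all(diff(fit$eigenvalues) <= 1e-12))

  # coincident points stay coincident
  pts2 <- rbind(pts, pts[1, ])
  fit2 <- pcoa(stats::dist(pts2), k = 2)
  expect_lt(max(abs(fit2$coordinates[1, ] - fit2$coordinates[6, ])), 1e-8)

  # non-Euclidean input (triangle-violating distances): negative
  # eigenvalues reported, their axes dropped
  dm <- matrix(c(0, 1, 3, 1, 0, 1, 3, 1, 0), 3)
  expect_warning(fitb <- pcoa(stats::as.dist(dm), k = 2), "negative")
  expect_true(any(fitb$eigenvalues < 0))
})

test_that("PERMANOVA separates separated clusters and respects relabeling", {
  set.seed(13)
  x <- rbind(matrix(rnorm(12, 0), 6, 2), matrix(rnorm(12, 50), 6, 2))
  g <- rep(c("a", "b"), each = 6)
  d <- stats::dist(x)
  res <- permanova(d, g, n_perm = 199, seed = 3)
  expect_equal(res$p_value, 1 / (1 + 199))
  expect_gt(res$pseudo_F, 100)

  # consistent permutation of samples and labels leaves pseudo-F unchanged
  perm <- sample(12)
  res2 <- permanova(stats::dist(x[perm, ]), g[perm], n_perm = 99, seed = 3)
  expect_equal(res2$pseudo_F, res$pseudo_F, tolerance = 1e-10)
})

test_that("Kruskal-Wallis wrapper matches the hand-computed example", {
  res <- kruskal_wallis(c(1, 2, 3, 4, 5, 6), rep(c("a", "b"), each = 3))
  expect_equal(round(res$H, 3), 3.857)
  # all values identical: tie-corrected H defined as 0 by convention
  tied <- kruskal_wallis(rep(5, 6), rep(c("a", "b"), each = 3))
  expect_equal(tied$H, 0)
  expect_equal(tied$p_value, 1)
})

test_that("TMM factors behave like trimmed-ratio normalization should", {
  set.seed(14)
  counts <- matrix(rnbinom(40 * 6, mu = 200, size = 10), 40, 6,
                   dimnames = list(sprintf("t%02d", 1:40),
                                   sprintf("s%d", 1:6)))
  f <- tmm_factors(counts)
  expect_equal(exp(mean(log(f))), 1, tolerance = 1e-10)

  # doubling every count of one sample is a pure library-size change:
  # its factor stays equal to the original sample's
  doubled <- cbind(counts, s7 = counts[, 1] * 2)
  f2 <- tmm_factors(doubled, reference = "s2")
  expect_equal(unname(f2["s7"] / f2["s1"]), 1, tolerance = 0.02)

  # composition outliers are trimmed away: after spiking 5% of taxa in half
  # the samples, TMM-normalized counts of the untouched taxa stay unbiased
  # between spiked and unspiked samples (within 5%)
  spiked <- counts
  spiked[1:2, 4:6] <- spiked[1:2, 4:6] * 8
  f3 <- tmm_factors(spiked)
  norm <- sweep(spiked, 2, colSums(spiked) * f3, "/")
  ratio <- rowMeans(norm[-(1:2), 4:6]) / rowMeans(norm[-(1:2), 1:3])
  expect_lt(abs(mean(ratio) - 1), 0.05)

  expect_error(tmm_factors(cbind(counts, z = 0)), "all-zero")
})

test_that("Wald DAA recovers planted fold changes and stays consistent", {
  d <- one_time_design(site = "skin")
  est <- power <- numeric(10)
  for (s in 1:10) {
    l2 <- stats::setNames(rep(2, 5), 1:5)
    sim <- generate_otu_counts(d, n_taxa = 40, mean_abundances = 500,
                               dispersion = 0.1, planted_log2fc = l2,
                               seed = s)
    g <- d$group[match(colnames(sim$otu$counts), d$sample_id)]
    res <- daa_wald(sim$otu$counts, g)
    hit <- match(sim$truth$taxon, res$taxon)
    est[s] <- mean(res$log2_fold_change[hit])
    power[s] <- mean(res$fdr_p[hit] < 0.05)
    # internal consistency
    expect_equal(res$fold_change, fold_change(res$log2_fold_change))
    expect_true(all(res$fdr_p >= res$wald_p - 1e-12))
    # BH monotonicity in the ranks of the raw p-values
    o <- order(res$wald_p)
    expect_true(all(diff(res$fdr_p[o]) >= -1e-12))
  }
  expect_lt(abs(mean(est) - 2), 0.5)
  expect_gt(mean(power), 0.8)
})

test_that("Wald DAA calibrates at group sizes where its asymptotics hold", {
  des <- data.frame(sample_id = sprintf("s%02d", 1:60),
                    fish_id = sprintf("f%02d", 1:60),
                    day = rep(1:30, each = 2),
                    group = rep(c("control", "treated"), 30),
                    time = "t3h", site = "skin")
  ps <- unlist(lapply(1:25, function(s) {
    sim <- generate_otu_counts(des, n_taxa = 20, mean_abundances = 200,
                               dispersion = 0.1, seed = s + 900)
    daa_wald(sim$otu$counts, des$group)$wald_p
  }))
  expect_lt(abs(mean(ps < 0.05) - 0.05), 0.03)
})

test_that("fold change reporting uses two significant figures", {
  expect_equal(fold_change(0), 1)
  expect_equal(fold_change(1), 2)
  expect_equal(fold_change(6.26), 77)
  expect_equal(fold_change(6.53), 92)
  expect_equal(fold_change(-1), 0.5)
})

test_that("the comparison runner emits the six stated contrasts per site design", {
  d <- one_time_design(n_days = 3, site = "skin")
  d24 <- one_time_design(n_days = 3, site = "skin", time = "t24h")
  d24$day <- d24$day - 3L  # reuse day labels is fine; sample ids differ
  d24$sample_id <- paste0(d24$sample_id, "_24")
  full <- rbind(d, d24)
  sim <- generate_otu_counts(full, n_taxa = 30, dispersion = 0.1, seed = 21)
  out <- run_comparisons(sim$otu, full, n_perm = 49, seed = 2,
                         rarefy_depth = NULL)
  expect_length(out$daa, 6)
  expect_true(all(c("skin.t3h.control_vs_treated",
                    "skin.t24h.control_vs_treated",
                    "skin.control.t3h_vs_t24h",
                    "skin.treated.t3h_vs_t24h",
                    "all_sites.t3h.control_vs_treated",
                    "all_sites.t24h.control_vs_treated") %in%
                    names(out$daa)))
  # pooled contrast uses all sites' samples of that time
  expect_length(out$permanova, 1)
  expect_true(is.finite(out$permanova$skin$pseudo_F))
  expect_equal(nrow(out$diversity$skin$alpha), 12)
})

test_that("planted group effects surface in the group contrast, not elsewhere", {
  d <- generate_design(4, "skin")
  l2 <- stats::setNames(rep(2.5, 4), 1:4)
  sim <- generate_otu_counts(d, n_taxa = 30, mean_abundances = 300,
                             dispersion = 0.05, planted_log2fc = l2,
                             seed = 31)
  out <- run_comparisons(sim$otu, d, n_perm = 49, seed = 3,
                         rarefy_depth = NULL)
  hits <- vapply(out$daa, function(r) sum(r$fdr_p < 0.05), 1L)
  group_contrasts <- grepl("control_vs_treated", names(hits))
  expect_gt(min(hits[group_contrasts]), 0)
  # time contrasts compare within group, where no effect was planted
  expect_lt(mean(hits[!group_contrasts]), mean(hits[group_contrasts]))
})

test_that("rarefaction drops shallow samples and fixes depth", {
  set.seed(15)
  counts <- matrix(rpois(20 * 4, 40), 20, 4,
                   dimnames = list(NULL, paste0("s", 1:4)))
  counts[, 4] <- 0
  counts[1, 4] <- 5
  expect_warning(r <- rarefy_counts(counts, depth = 500, seed = 1),
                 "below depth")
  expect_equal(unname(colSums(r)), rep(500, 3))
  expect_identical(rarefy_counts(counts[, 1:3], 500, seed = 9),
                   rarefy_counts(counts[, 1:3], 500, seed = 9))
})

test_that("relative abundance table reports percent per stratum", {
  d <- one_time_design(n_days = 3, site = "skin")
  sim <- generate_otu_counts(d, n_taxa = 12, seed = 5)
  tab <- relative_abundance_table(sim$otu, d, top = 5)
  expect_equal(nrow(tab), 10)  # 2 strata x top 5
  for (st in split(tab, paste(tab$group, tab$time))) {
    expect_true(all(diff(st$abundance_pct) <= 0))
    expect_lte(sum(st$abundance_pct), 100 + 1e-9)
  }
})
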