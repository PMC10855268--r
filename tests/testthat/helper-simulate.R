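# Shared builders for small synthetic analysis sets.

# One-site design restricted to one exposure time (n_days day-pairs).
one_time_design <- function(n_days = 6, site = "muscle", time = "t3h") {
  d <- generate_design(n_days, site)
  d[d$time == time, , drop = FALSE]
}

# Pair-centered fused dataset + design + truth for one analysis set.
sim_fused <- function(seed, block_sizes = c(metabolomics = 60),
                      n_planted = 5, effect_size = 3, day_effect_sd = 1,
                      noise_sd = 1, n_days = 6) {
  d <- one_time_design(n_days)
  spec <- synthetic_spec(block_sizes = block_sizes, n_planted = n_planted,
                         effect_size = effect_size,
                         day_effect_sd = day_effect_sd, noise_sd = noise_sd,
                         seed = seed)
  sim <- generate_multiomics(d, spec)
  centered <- lapply(sim$blocks, pair_center, design = d)
  fused <- fuse(centered, d)
  yd <- d[match(fused$sample_ids, d$sample_id), , drop = FALSE]
  list(fused = fused, design = yd, y = yd$group, day = yd$day,
       truth = sim$truth, blocks = sim$blocks)
}

# Per-feature paired/two-sample t statistics (vectorized), used as an
# independent ranking oracle.
col_t_stats <- function(x, y) {
  g1 <- x[y == "treated", , drop = FALSE]
  g0 <- x[y == "control", , drop = FALSE]
  n1 <- nrow(g1); n0 <- nrow(g0)
  m <- colMeans(g1) - colMeans(g0)
  v1 <- apply(g1, 2, stats::var); v0 <- apply(g0, 2, stats::var)
  m / sqrt(v1 / n1 + v0 / n0)
}
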