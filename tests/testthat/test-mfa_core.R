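# independent oracle: eigendecomposition of the sample covariance matrix
eigen_pca_oracle <- function(x) {
  ev <- eigen(stats::cov(x), symmetric = TRUE)
  scores <- x %*% ev$vectors
  list(eigenvalues = ev$values, scores = scores)
}

test_that("pca matches closed-form and oracle expectations", {
  # points on the line y = x: first axis along (1,1)/sqrt(2), second flat
  x <- cbind(c(-2, -1, 0, 1, 2), c(-2, -1, 0, 1, 2))
  fit <- pca(x)
  expect_equal(abs(fit$loadings[, 1]), rep(1 / sqrt(2), 2), tolerance = 1e-10)
  expect_equal(length(fit$eigenvalues), 2)
  expect_lt(fit$eigenvalues[2], 1e-20)

  # trace identity on a random matrix
  set.seed(31)
  m <- scale(matrix(rnorm(12 * 30), 12, 30), scale = FALSE)
  fit <- pca(m)
  expect_equal(sum(fit$eigenvalues), sum(apply(m, 2, stats::var)),
               tolerance = 1e-10)
  # full reconstruction
  recon <- fit$scores %*% t(fit$loadings)
  expect_lt(max(abs(recon - m)), 1e-10)
  # eigenvalues non-increasing, scores orthogonal
  expect_true(all(diff(fit$eigenvalues) <= 1e-12))
  g <- crossprod(fit$scores)
  expect_lt(max(abs(g[upper.tri(g)])), 1e-8 * max(diag(g)))

  # scores agree with an independent eigendecomposition up to column sign
  for (s in 1:20) {
    set.seed(s)
    m <- scale(matrix(rnorm(8 * 5), 8, 5), scale = FALSE)
    fit <- pca(m)
    orc <- eigen_pca_oracle(m)
    for (a in 1:5) {
      if (orc$eigenvalues[a] < 1e-10) next
      expect_equal(abs(fit$scores[, a]), abs(orc$scores[, a]),
                   tolerance = 1e-8, ignore_attr = TRUE)
    }
    expect_equal(fit$eigenvalues, orc$eigenvalues, tolerance = 1e-8)
  }

  expect_error(pca(matrix(1:4, 1)), ">= 2 samples")
  expect_error(pca(matrix(c(1, 2, 5, 9), 2)), "centered")
})

test_that("block weights equalize first-axis inertia", {
  set.seed(7)
  x <- scale(matrix(rnorm(10 * 6), 10, 6))
  l1 <- pca(x)$eigenvalues[1]
  expect_equal(block_weight(x), 1 / l1, tolerance = 1e-12)
  expect_equal(block_weight(x * 2), 1 / (4 * l1), tolerance = 1e-10)

  # post-weighting first eigenvalue is 1, over random blocks
  for (s in 1:20) {
    set.seed(s + 100)
    b <- scale(matrix(rnorm(9 * (3 + s %% 5)), 9))
    w <- block_weight(b)
    expect_equal(pca(b * sqrt(w))$eigenvalues[1], 1, tolerance = 1e-8)
  }
  expect_error(block_weight(matrix(0, 5, 3)), "degenerate")
})

test_that("qualitative encoding follows the correspondence-analysis metric", {
  cl <- rep(c("a", "b", "c", "d"), each = 6)
  enc <- encode_qualitative(cl)
  expect_equal(dim(enc), c(24, 4))
  expect_lt(max(abs(colMeans(enc))), 1e-12)
  # balanced 4 classes: indicator scaled by 1/sqrt(1/4) = 2 before centering
  expect_equal(max(enc), 2 * (1 - 1 / 4), tolerance = 1e-12)
  # 2 samples, 2 levels: centered encoding has rank 1
  expect_equal(qr(encode_qualitative(c("x", "y")))$rank, 1)
  expect_error(encode_qualitative(rep("only", 5)), ">= 2 levels")
  expect_error(encode_qualitative(factor(c("a", "a", "b"),
                                         levels = c("a", "b", "z"))),
               "zero samples")
})

test_that("single-block MFA reduces to PCA of the weighted block", {
  set.seed(12)
  x <- scale(matrix(rnorm(12 * 20), 12, 20))
  colnames(x) <- sprintf("f%02d", 1:20)
  res <- mfa_fit(list(metabolomics = x), n_dims = 4)
  ref <- pca(x * sqrt(block_weight(x)), n_comp = 4)
  for (a in 1:4) {
    r <- abs(stats::cor(res$scores[, a], ref$scores[, a]))
    expect_gt(r, 1 - 1e-8)
  }
})

test_that("MFA balances blocks and normalizes contributions", {
  set.seed(3)
  x <- scale(matrix(rnorm(12 * 15), 12, 15))
  colnames(x) <- sprintf("f%02d", 1:15)
  res <- mfa_fit(list(a = x, b = x), n_dims = 3)
  # two identical blocks split every dimension's contribution 50/50
  expect_equal(unname(res$block_contributions["a", ]),
               unname(res$block_contributions["b", ]), tolerance = 1e-8)
  expect_equal(unname(colSums(res$block_contributions)), rep(100, 3),
               tolerance = 1e-8)
  expect_equal(unname(colSums(res$variable_contributions)), rep(100, 3),
               tolerance = 1e-8)
  expect_true(all(diff(res$eigenvalues) <= 1e-12))

  # permuting sample order permutes score rows identically
  set.seed(5)
  y <- scale(matrix(rnorm(12 * 10), 12, 10))
  rownames(y) <- sprintf("s%02d", 1:12)
  colnames(y) <- sprintf("g%02d", 1:10)
  perm <- sample(12)
  r1 <- mfa_fit(list(m = y), n_dims = 3)
  r2 <- mfa_fit(list(m = y[perm, ]), n_dims = 3)
  expect_equal(r2$scores, r1$scores[perm, ], tolerance = 1e-10)
})

test_that("the class-active qualitative block is weighted like any block", {
  set.seed(9)
  x <- scale(matrix(rnorm(24 * 30), 24, 30))
  colnames(x) <- sprintf("f%02d", 1:30)
  cl <- rep(c("t3h control", "t3h treated", "t24h control", "t24h treated"),
            each = 6)
  res <- mfa_fit(list(m = x), classes = cl, n_dims = 3)
  enc <- encode_qualitative(cl)
  expect_equal(unname(res$block_weights["classes"]),
               1 / pca(enc)$eigenvalues[1], tolerance = 1e-10)
  expect_equal(nrow(res$block_contributions), 2)
  # supplementary mode leaves the solution to the quantitative blocks alone
  sup <- mfa_fit(list(m = x), classes = cl, n_dims = 3, class_active = FALSE)
  ref <- mfa_fit(list(m = x), n_dims = 3)
  expect_equal(sup$scores, ref$scores, tolerance = 1e-10)
  expect_false(is.null(sup$class_projection))
})

test_that("a planted effect concentrated in one block dominates its contribution", {
  hits <- hits_sep <- 0
  for (s in 1:20) {
    d <- one_time_design()
    spec <- synthetic_spec(block_sizes = c(lipidomics = 40, metabolomics = 40),
                           n_planted = c(lipidomics = 10, metabolomics = 0),
                           effect_size = 3, seed = s + 40)
    sim <- generate_multiomics(d, spec)
    scaled <- lapply(sim$blocks, function(b)
      autoscale(pair_center(b, d)$matrix)$matrix)
    y <- d$group[match(rownames(scaled[[1]]), d$sample_id)]
    res <- mfa_fit(scaled, classes = y, n_dims = 3)
    # the discriminating dimension: the one whose scores separate the groups
    sep <- which.max(abs(vapply(1:3, function(a)
      stats::t.test(res$scores[y == "treated", a],
                    res$scores[y == "control", a])$statistic, numeric(1))))
    ctr <- res$block_contributions[c("lipidomics", "metabolomics"), sep]
    if (ctr["lipidomics"] > ctr["metabolomics"]) hits <- hits + 1
  }
  expect_gte(hits / 20, 0.95)
})

test_that("four planted classes separate in the first two MFA dimensions", {
  silhouette_mean <- function(xy, lab) {
    dm <- as.matrix(stats::dist(xy))
    mean(vapply(seq_along(lab), function(i) {
      a <- mean(dm[i, lab == lab[i]][-which(which(lab == lab[i]) == i)])
      b <- min(vapply(setdiff(unique(lab), lab[i]),
                      function(l) mean(dm[i, lab == l]), numeric(1)))
      (b - a) / max(a, b)
    }, numeric(1)))
  }
  hits <- 0
  for (s in 1:20) {
    d <- generate_design(6, "muscle")
    # distinct effects at 3 h and 24 h: simulate each time point separately
    sims <- lapply(c(t3h = 101, t24h = 202), function(off) {
      generate_multiomics(d[d$time == ifelse(off == 101, "t3h", "t24h"), ],
                          synthetic_spec(block_sizes = c(m = 50),
                                         n_planted = 10, effect_size = 3,
                                         seed = s + off))
    })
    x <- rbind(sims$t3h$blocks$m$matrix, sims$t24h$blocks$m$matrix)
    x <- x[d$sample_id, ]
    scaled <- autoscale(pair_center(x, d))$matrix
    cl <- paste(d$time, d$group)[match(rownames(scaled), d$sample_id)]
    res <- mfa_fit(list(m = scaled), classes = cl, n_dims = 2)
    if (silhouette_mean(res$scores[, 1:2], cl) > 0) hits <- hits + 1
  }
  expect_gte(hits / 20, 0.95)
})
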