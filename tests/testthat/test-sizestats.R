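test_that("centroid-size ANOVA matches direct sum-of-squares computation", {
  set.seed(1)
  # two groups: F equals the squared pooled-variance t statistic
  x <- rnorm(12, 10); y <- rnorm(15, 11)
  a <- anova_centroid_size(c(x, y), rep(c("a", "b"), c(12, 15)))
  tt <- t.test(x, y, var.equal = TRUE)
  expect_equal(a$f_statistic, unname(tt$statistic)^2, tolerance = 1e-10)
  expect_equal(a$p_value, tt$p.value, tolerance = 1e-10)
  # explicit sum-of-squares oracle, equal n and equal means
  g <- rep(letters[1:4], each = 6)
  v <- rnorm(24, 5)
  a2 <- anova_centroid_size(v, g)
  gm <- tapply(v, g, mean)
  ssb <- sum(6 * (gm - mean(v))^2)
  ssw <- sum((v - gm[g])^2)
  expect_equal(a2$f_statistic, (ssb / 3) / (ssw / 20), tolerance = 1e-10)
  expect_error(anova_centroid_size(1:3, c("a", "a", "b")), ">= 2")
})

test_that("ANOVA holds its nominal type-I error across many species", {
  set.seed(42)
  n_rep <- 400
  rej <- 0
  labels <- rep(paste0("s", 1:19), each = 10)
  for (r in seq_len(n_rep)) {
    v <- rnorm(190)
    rej <- rej + (anova_centroid_size(v, labels)$p_value < 0.05)
  }
  expect_gte(rej / n_rep, 0.03)
  expect_lte(rej / n_rep, 0.07)
})

test_that("Bonferroni-adjusted pairwise t-tests follow the definition", {
  set.seed(2)
  v <- rnorm(40, rep(c(0, 0.2, 3, 10), each = 10))
  g <- rep(letters[1:4], each = 10)
  adj <- pairwise_t_bonferroni(v, g)
  expect_equal(adj, t(adj))
  expect_equal(diag(adj), rep(1, 4), ignore_attr = TRUE)
  m <- 6   # 4 groups -> 6 comparisons
  raw_ab <- t.test(v[g == "a"], v[g == "b"], var.equal = TRUE)$p.value
  expect_equal(adj["a", "b"], min(1, m * raw_ab), tolerance = 1e-12)
  expect_true(all(adj <= 1))
  # adjusted >= raw for every pair
  for (p in list(c("a", "c"), c("b", "d"))) {
    raw <- t.test(v[g == p[1]], v[g == p[2]], var.equal = TRUE)$p.value
    expect_gte(adj[p[1], p[2]], raw)
  }
})

test_that("allometry permutation test is exact on the p-value grid", {
  set.seed(3)
  n <- 30
  sizes <- exp(rnorm(n, 1, 0.2))
  x <- log(sizes) - mean(log(sizes))
  # shape depends exactly linearly on log CS: R2 = 1, p at the grid minimum
  shapes <- outer(x, c(1, -2, 0.5))
  r <- allometry_test(shapes, sizes, n_permutations = 500, seed = 1)
  expect_equal(r$r_squared, 1, tolerance = 1e-12)
  expect_equal(r$p_value, 1 / 501, tolerance = 1e-12)
  # determinism under a fixed seed
  shapes2 <- shapes + matrix(rnorm(n * 3, 0, 0.5), n, 3)
  r1 <- allometry_test(shapes2, sizes, 199, seed = 9)
  r2 <- allometry_test(shapes2, sizes, 199, seed = 9)
  expect_identical(r1$p_value, r2$p_value)
  # R2 identity: R2 = 1 - SS_resid / SS_total
  Y <- sweep(shapes2, 2, colMeans(shapes2))
  b <- crossprod(Y, x) / sum(x^2)
  ss_res <- sum((Y - outer(x, as.vector(b)))^2)
  expect_equal(r1$r_squared, 1 - ss_res / sum(Y^2), tolerance = 1e-12)
  # p-values live on the grid i/(n_perm + 1)
  expect_equal(r1$p_value * 200, round(r1$p_value * 200), tolerance = 1e-9)
  expect_error(allometry_test(shapes2, rep(2, n)), "constant")
})

test_that("Procrustes variance matches a brute-force loop and scales", {
  set.seed(4)
  X <- matrix(rnorm(60), 10, 6)
  lab <- rep(c("a", "b"), each = 5)
  dv <- shape_variance(X, lab)
  for (g in c("a", "b")) {
    M <- X[lab == g, ]
    mu <- colMeans(M)
    v <- mean(apply(M, 1, function(r) sum((r - mu)^2)))
    expect_equal(unname(dv$per_group_variance[g]), v, tolerance = 1e-12)
  }
  # identical members: zero variance
  expect_equal(unname(shape_variance(X[rep(1, 4), ],
               rep("z", 4))$per_group_variance), 0)
  # doubling deviations quadruples the variance
  mu_a <- colMeans(X[lab == "a", ])
  X2 <- X
  X2[lab == "a", ] <- sweep(sweep(X[lab == "a", ], 2, mu_a), 1, 2, "*") +
    rep(mu_a, each = 5)
  dv2 <- shape_variance(X2, lab)
  expect_equal(unname(dv2$per_group_variance["a"]),
               4 * unname(dv$per_group_variance["a"]), tolerance = 1e-12)
  # invariant to specimen order
  o <- sample(10)
  dv3 <- shape_variance(X[o, ], lab[o])
  expect_equal(dv3$per_group_variance[sort(names(dv3$per_group_variance))],
               dv$per_group_variance[sort(names(dv$per_group_variance))],
               tolerance = 1e-12)
  expect_warning(shape_variance(X, c(rep("a", 9), "solo")), "singleton")
})

test_that("observer error report separates digitization from biology", {
  sim <- simulate_landmark_dataset(small_design(), seed = 5)
  # replicates identical to originals: observer variance exactly 0
  reps0 <- simulate_observer_replicates(sim$dataset, 3, 4, sigma_obs = 0,
                                        seed = 1)
  r0 <- observer_error_report(sim$dataset, reps0)
  expect_lt(r0$observer_variance, 1e-20)
  expect_equal(r0$ratio, r0$observer_variance / r0$species_variance)
  # bookkeeping: 4 species x 3 specimens repeated
  expect_equal(r0$n_repeated_specimens, 12)
  expect_equal(n_specimens(reps0), 4 * 3 * 4)
  expect_error(observer_error_report(sim$dataset, sim$dataset),
               "observer ids")
})
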