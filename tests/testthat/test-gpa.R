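test_that("centroid size follows its closed form", {
  sq <- rbind(c(0, 0), c(1, 0), c(1, 1), c(0, 1))
  expect_equal(centroid_size(sq), sqrt(2), tolerance = 1e-12)
  # homogeneity: scaling by c scales CS by exactly c
  expect_equal(centroid_size(sq * 3.7), 3.7 * sqrt(2), tolerance = 1e-12)
  # independent two-step recomputation on the wing template
  tmpl <- default_wing_template() * 2.5 + 1
  ctr <- colMeans(tmpl)
  expect_equal(centroid_size(tmpl),
               sqrt(sum(apply(tmpl, 1, function(p) sum((p - ctr)^2)))),
               tolerance = 1e-12)
})

test_that("pairwise alignment finds the optimal similarity transform", {
  tri <- rbind(c(0, 0), c(1, 0), c(0, 1))
  self <- align_pair(tri, tri)
  expect_equal(self$distance, 0, tolerance = 1e-12)
  # rotation + translation removed exactly
  tar <- sweep(tri %*% rot_mat(pi / 2), 2, c(5, -3), "+")
  expect_lt(align_pair(tri, tar)$distance, 1e-10)
  # grid-search oracle at 1e-4 rad resolution
  b <- rbind(c(0, 0), c(2, 0), c(1, 2))
  expect_equal(align_pair(tri, b)$distance,
               oracle_procrustes_distance(tri, b), tolerance = 1e-4)
  expect_error(align_pair(tri, rbind(c(0, 0), c(1, 0))), "equal k")
  expect_error(align_pair(tri, matrix(1, 3, 2)), "degenerate")
})

test_that("GPA aligns exact copies perfectly and is similarity-invariant", {
  set.seed(11)
  tmpl <- default_wing_template()
  # one shape duplicated under random similarity transforms
  copies <- lapply(1:8, function(i) similarity_transform(tmpl))
  g <- generalized_procrustes(landmark_dataset(copies))
  dev <- apply(g$coords, 3, function(m) sum((m - g$consensus)^2))
  expect_lt(sum(dev), 1e-16)
  # invariance: re-transforming every configuration changes nothing
  sim <- simulate_landmark_dataset(small_design(), seed = 4)
  g1 <- generalized_procrustes(sim$dataset)
  moved <- lapply(seq_len(n_specimens(sim$dataset)), function(i)
    similarity_transform(sim$dataset$coords[, , i]))
  g2 <- generalized_procrustes(landmark_dataset(moved, sim$dataset$meta))
  expect_lt(max(abs(g1$coords - g2$coords)), 1e-6)
  # every aligned specimen has unit centroid size
  cs <- apply(g1$coords, 3, centroid_size)
  expect_true(all(abs(cs - 1) < 1e-9))
  expect_true(all(abs(apply(g1$coords, 3, colMeans)) < 1e-9))
  expect_equal(centroid_size(g1$consensus), 1, tolerance = 1e-9)
})

test_that("two-specimen GPA agrees with pairwise alignment", {
  # for nearby shapes the chord distance between the pair equals the sum of
  # their distances to the consensus up to third-order curvature terms
  set.seed(5)
  a <- default_wing_template() + matrix(rnorm(36, 0, 0.002), 18, 2)
  b <- default_wing_template() + matrix(rnorm(36, 0, 0.002), 18, 2)
  g <- generalized_procrustes(landmark_dataset(list(a, b)))
  d_pair <- align_pair(a, b)$distance
  d_cons <- sum(apply(g$coords, 3, function(m)
    align_pair(g$consensus, m)$distance))
  expect_lt(abs(d_pair - d_cons), 1e-6)
})

test_that("Procrustes distance behaves as a pseudo-metric", {
  set.seed(6)
  shapes <- lapply(1:6, function(i)
    default_wing_template() + matrix(rnorm(36, 0, 0.05), 18, 2))
  d <- function(a, b) align_pair(a, b)$distance
  for (tr in list(c(1, 2, 3), c(2, 4, 6), c(1, 5, 3))) {
    a <- shapes[[tr[1]]]; b <- shapes[[tr[2]]]; c <- shapes[[tr[3]]]
    expect_equal(d(a, b), d(b, a), tolerance = 1e-9)
    expect_lte(d(a, c), d(a, b) + d(b, c) + 1e-9)
  }
  expect_equal(d(shapes[[1]], similarity_transform(shapes[[1]])), 0,
               tolerance = 1e-8)
})

test_that("tangent projection fixes the consensus and contracts residuals", {
  sim <- simulate_landmark_dataset(small_design(sigma_w = 0.005), seed = 7)
  g <- generalized_procrustes(sim$dataset)
  X <- tangent_projection(g)
  cvec <- as.vector(t(g$consensus))
  # the consensus is a fixed point of the projection
  proj_cons <- cvec + (1 - sum(cvec * cvec)) * cvec
  expect_equal(proj_cons, cvec, tolerance = 1e-12)
  Xraw <- tangent_projection(g, project = FALSE)
  for (i in seq_len(nrow(X))) {
    expect_lte(sqrt(sum((X[i, ] - cvec)^2)),
               sqrt(sum((Xraw[i, ] - cvec)^2)) + 1e-12)
  }
  # low noise: tangent distances track exact Procrustes distances within 1%
  idx <- utils::combn(6, 2)
  for (j in seq_len(ncol(idx))) {
    i1 <- idx[1, j]; i2 <- idx[2, j]
    dt <- sqrt(sum((X[i1, ] - X[i2, ])^2))
    dp <- align_pair(g$coords[, , i1], g$coords[, , i2])$distance
    expect_equal(dt, dp, tolerance = 0.01)
  }
})

test_that("group mean shapes recover known displacements", {
  g0 <- generalized_procrustes(landmark_dataset(
    lapply(1:3, function(i) default_wing_template())))
  expect_lt(align_pair(default_wing_template(), mean_shape(g0))$distance,
            1e-8)
  # mean over all specimens equals the consensus
  sim <- simulate_landmark_dataset(small_design(), seed = 8)
  g <- generalized_procrustes(sim$dataset)
  expect_equal(mean_shape(g), g$consensus, tolerance = 1e-6,
               ignore_attr = TRUE)
  # two groups, landmark 5 displaced by +0.05 in x in group B
  set.seed(9)
  n <- 40; sw <- 0.005
  tmpl <- default_wing_template()
  mk <- function(displaced) {
    m <- tmpl
    if (displaced) m[5, 1] <- m[5, 1] + 0.05
    similarity_transform(m + matrix(rnorm(36, 0, sw), 18, 2))
  }
  coords <- c(lapply(1:n, function(i) mk(FALSE)),
              lapply(1:n, function(i) mk(TRUE)))
  meta <- data.frame(specimen = paste0("s", 1:(2 * n)),
                     species = rep(c("A", "B"), each = n))
  g2 <- generalized_procrustes(landmark_dataset(coords, meta))
  diffvec <- mean_shape(g2, "B") - mean_shape(g2, "A")
  # mean difference at landmark 5 recovers the shift direction and size
  se <- sw * sqrt(2 / n)
  expect_lt(abs(sqrt(sum(diffvec[5, ]^2)) - 0.05 / centroid_size(tmpl)),
            3 * se + 0.004)
  expect_error(mean_shape(g2, "no_such_group"), "empty")
})
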