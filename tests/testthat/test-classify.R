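test_that("rank reduction is an isometry with an orthonormal basis", {
  sim <- simulate_landmark_dataset(small_design(), seed = 1)
  g <- generalized_procrustes(sim$dataset)
  X <- tangent_projection(g)
  red <- reduce_rank(X)
  expect_lte(ncol(red$scores), 2 * 18 - 4)
  d0 <- dist(X); d1 <- dist(red$scores)
  expect_equal(as.vector(d1), as.vector(d0), tolerance = 1e-9)
  back <- red$scores %*% t(red$rotation) + rep(red$center,
                                               each = nrow(X))
  expect_equal(unclass(back), unclass(X)[, ], tolerance = 1e-9,
               ignore_attr = TRUE)
  expect_error(reduce_rank(matrix(1, 5, 3)), "zero total variance")
})

test_that("LDA reproduces the explicit Mahalanobis decision rule", {
  set.seed(2)
  for (rep in 1:5) {
    p <- sample(2:5, 1); g <- sample(2:4, 1)
    n <- g * sample(8:15, 1)
    lab <- rep(letters[1:g], length.out = n)
    X <- matrix(rnorm(n * p), n, p) +
      matrix(rnorm(g * p, sd = 2), g, p)[match(lab, letters[1:g]), ]
    fit <- fit_lda(X, lab, reduce = FALSE)
    pred <- predict(fit, X)
    expect_equal(as.character(pred$class), oracle_lda_predict(X, lab, X))
    expect_equal(rowSums(pred$posterior), rep(1, n), tolerance = 1e-12)
  }
})

test_that("LDA agrees with the reference discriminant implementation", {
  skip_if_not_installed("MASS")
  set.seed(3)
  lab <- rep(c("a", "b", "c"), each = 15)
  X <- matrix(rnorm(45 * 4), 45, 4) +
    matrix(rnorm(12, sd = 1.5), 3, 4)[match(lab, c("a", "b", "c")), ]
  fit <- fit_lda(X, lab, reduce = FALSE)
  m <- MASS::lda(X, grouping = lab)
  expect_equal(as.character(predict(fit, X)$class),
               as.character(predict(m, X)$class))
})

test_that("posteriors behave at symmetric and extreme queries", {
  set.seed(4)
  X <- rbind(matrix(rnorm(40), 20, 2) + 5, matrix(rnorm(40), 20, 2) - 5)
  lab <- rep(c("hi", "lo"), each = 20)
  fit <- fit_lda(X, lab, reduce = FALSE)
  mid <- matrix((colMeans(X[1:20, ]) + colMeans(X[21:40, ])) / 2, 1)
  post <- predict(fit, mid)$posterior
  expect_equal(as.vector(post), c(0.5, 0.5), tolerance = 0.05)
  # moving toward one mean drives its posterior monotonically to 1
  dirv <- colMeans(X[1:20, ]) - as.vector(mid)
  ps <- sapply(seq(0, 3, by = 0.5), function(s)
    predict(fit, mid + s * rep(dirv, each = 1))$posterior[, "hi"])
  expect_true(all(diff(ps) > -1e-12))
  expect_gt(ps[length(ps)], 0.999)
})

test_that("LOOCV confusion matrices are exact on separable data and honest under the null", {
  sim <- simulate_landmark_dataset(small_design(), seed = 5)  # delta/sigma_w = 8
  g <- generalized_procrustes(sim$dataset)
  X <- tangent_projection(g)
  cm <- loocv_confusion(X, g$meta$species)
  expect_equal(cm$accuracy, 1)
  expect_equal(unname(rowSums(cm$counts)),
               unname(as.vector(table(g$meta$species))))
  expect_equal(sum(cm$counts), n_specimens(sim$dataset))
  # label permutation: accuracy near chance sum((n_g/n)^2)
  set.seed(6)
  n <- 36; lab <- rep(c("a", "b", "c"), each = 12)
  Xn <- matrix(rnorm(n * 4), n, 4)
  accs <- replicate(60, {
    loocv_confusion(Xn, sample(lab), priors = "proportional")$accuracy
  })
  chance <- sum((table(lab) / n)^2)
  se <- sd(accs) / sqrt(length(accs))
  expect_lt(abs(mean(accs) - chance), 3 * se + 0.05)
  expect_error(loocv_confusion(Xn[1:13, ], c(rep("a", 12), "b")), "size 1")
})

test_that("collapsing species confusion to genus can only help", {
  cm <- confusion_matrix(
    factor(c("a1", "a1", "a2", "a2", "b1", "b1", "b2", "b2")),
    factor(c("a1", "a2", "a2", "a2", "b1", "b1", "b2", "b2"),
           levels = c("a1", "a2", "b1", "b2")), rank = "species")
  map <- c(a1 = "A", a2 = "A", b1 = "B", b2 = "B")
  gcm <- collapse_to_genus(cm, map)
  expect_equal(gcm$accuracy, 1)          # the error was within genus A
  expect_equal(cm$accuracy, 7 / 8)
  expect_gte(gcm$accuracy, cm$accuracy)
  # identity map leaves the matrix unchanged
  idm <- stats::setNames(rownames(cm$counts), rownames(cm$counts))
  expect_equal(collapse_to_genus(cm, idm)$counts[rownames(cm$counts),
                                                 colnames(cm$counts)],
               cm$counts, ignore_attr = TRUE)
  expect_error(collapse_to_genus(cm, map[-1]), "cover")
})

test_that("CVA distances obey the Mahalanobis closed form and invariances", {
  set.seed(7)
  # identity pooled covariance: distances equal Euclidean between means
  n <- 400
  X <- matrix(rnorm(2 * n * 3), 2 * n, 3)
  X[1:n, 1] <- X[1:n, 1] + 4
  lab <- rep(c("a", "b"), each = n)
  cv <- cva(X, lab)
  mu_d <- colMeans(X[1:n, ]) - colMeans(X[(n + 1):(2 * n), ])
  pw <- wingmorph:::pooled_within(reduce_rank(X)$scores, factor(lab))
  expect_equal(ncol(cv$scores), 1)        # g - 1 axes
  d2_oracle <- drop(t(pw$means[1, ] - pw$means[2, ]) %*%
                      solve(pw$cov) %*% (pw$means[1, ] - pw$means[2, ]))
  expect_equal(cv$mahalanobis["a", "b"]^2, d2_oracle, tolerance = 1e-9)
  expect_equal(cv$mahalanobis["a", "b"], cv$mahalanobis["b", "a"])
  expect_equal(diag(cv$mahalanobis), c(a = 0, b = 0))
  # affine invariance of Mahalanobis distances
  A <- matrix(rnorm(9), 3, 3) + diag(3)
  cv2 <- cva(X %*% A, lab)
  expect_equal(cv2$mahalanobis, cv$mahalanobis, tolerance = 1e-6)
})
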