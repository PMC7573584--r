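#' Rank reduction of shape variables by principal components
#'
#' Procrustes shape coordinates of k 2-D landmarks span at most 2k - 4
#' dimensions (translation, scale and rotation are removed), so the raw
#' 2k-column shape matrix has a singular covariance and cannot feed a
#' discriminant analysis directly. This projects the data onto the principal
#' components whose eigenvalues exceed `tol` times the largest, an isometry
#' on the observed data that makes the pooled covariance invertible.
#'
#' @param shapes `n x p` shape matrix
#' @param tol relative eigenvalue tolerance (default 1e-10)
#' @param max_rank optional cap on the number of retained components (used
#'   by the classifier so the pooled within-group covariance stays
#'   invertible when specimens are scarce)
#' @return list with `scores` (`n x r` reduced matrix), `rotation`
#'   (`p x r` orthonormal basis), `center` (length-p column means)
#' @export
reduce_rank <- function(shapes, tol = 1e-10, max_rank = Inf) {
  X <- as.matrix(shapes)
  if (nrow(X) < 2) stop("need at least 2 rows")
  ctr <- colMeans(X)
  Xc <- sweep(X, 2, ctr)
  sv <- svd(Xc)
  ev <- sv$d^2
  if (ev[1] <= 0) stop("zero total variance: nothing to reduce")
  keep <- ev > tol * ev[1]
  r <- max(1L, min(sum(keep), max_rank))
  list(scores = Xc %*% sv$v[, seq_len(r), drop = FALSE],
       rotation = sv$v[, seq_len(r), drop = FALSE],
       center = ctr)
}

# Pooled within-group covariance and group means on a full-rank matrix.
pooled_within <- function(X, labels) {
  lev <- levels(labels)
  g <- length(lev); n <- nrow(X); p <- ncol(X)
  means <- matrix(0, g, p, dimnames = list(lev, colnames(X)))
  W <- matrix(0, p, p)
  for (gr in lev) {
    M <- X[labels == gr, , drop = FALSE]
    mu <- colMeans(M)
    means[gr, ] <- mu
    W <- W + crossprod(sweep(M, 2, mu))
  }
  list(means = means, cov = W / (n - g), n_per_group = table(labels))
}

#' Fit a linear discriminant classifier on shape variables
#'
#' Classical Gaussian LDA: group means plus one pooled within-group
#' covariance on rank-reduced shape variables; the decision rule assigns a
#' specimen to the group maximizing `ln(prior) - Mahalanobis^2 / 2`.
#' Priors default to group-frequency proportional (the behavior of the
#' standard R discriminant tooling); with species sample sizes ranging from
#' 14 to 30 this choice matters at the margin, so uniform priors are
#' available.
#'
#' @param shapes `n x p` shape matrix (raw shape variables; rank reduction
#'   is applied internally) or an already-reduced matrix with
#'   `reduce = FALSE`
#' @param labels group labels, length n, every group with >= 2 members
#' @param priors `"proportional"` or `"uniform"`
#' @param reduce apply [reduce_rank()] first (default `TRUE`)
#' @return object of class `wing_lda`: `means`, `cov`, `chol` (Cholesky of
#'   the pooled covariance), `priors`, `levels`, `reduction` (or `NULL`)
#' @export
fit_lda <- function(shapes, labels, priors = c("proportional", "uniform"),
                    reduce = TRUE) {
  priors <- match.arg(priors)
  labels <- factor(labels)
  cnt <- table(labels)
  if (any(cnt < 2))
    stop("group(s) with a single specimen cannot be fit: ",
         paste(names(cnt)[cnt < 2], collapse = ", "))
  red <- NULL
  X <- as.matrix(shapes)
  g0 <- nlevels(labels)
  if (reduce) {
    red <- reduce_rank(X, max_rank = nrow(X) - g0 - 1L)
    X <- red$scores
  }
  n <- nrow(X); p <- ncol(X); g <- nlevels(labels)
  if (reduce && n <= p + g)
    warning("few specimens (", n, ") relative to dimensions (", p,
            ") + groups (", g, "): covariance estimate is unstable")
  pw <- pooled_within(X, labels)
  ch <- tryCatch(chol(pw$cov), error = function(e) NULL)
  if (is.null(ch))
    stop("pooled within-group covariance is singular after reduction; ",
         "reduce dimensionality further (larger tol in reduce_rank)")
  pr <- if (priors == "proportional") as.numeric(cnt) / n
        else rep(1 / g, g)
  names(pr) <- levels(labels)
  structure(list(means = pw$means, cov = pw$cov, chol = ch, priors = pr,
                 levels = levels(labels), reduction = red,
                 n = n, p = p),
            class = "wing_lda")
}

#' @export
print.wing_lda <- function(x, ...) {
  cat("Linear discriminant model: ", length(x$levels), " groups, ",
      x$p, " variables, n = ", x$n, "\n", sep = "")
  cat("Priors: ", paste(sprintf("%s=%.3f", x$levels, x$priors),
                        collapse = ", "), "\n", sep = "")
  invisible(x)
}

#' Classify shape configurations with a fitted discriminant model
#'
#' @param object a `wing_lda` model
#' @param newdata matrix of rows in the model's input space (raw shape
#'   variables if the model was fit with reduction, else reduced variables)
#' @param ... unused
#' @return list with `class` (factor of predicted labels; exact posterior
#'   ties resolve to the lexicographically lowest label) and `posterior`
#'   (`n x g` matrix, rows summing to 1)
#' @export
predict.wing_lda <- function(object, newdata, ...) {
  X <- as.matrix(newdata)
  if (!is.null(object$reduction)) {
    if (ncol(X) != length(object$reduction$center))
      stop("dimension mismatch: expected ", length(object$reduction$center),
           " shape variables, got ", ncol(X))
    X <- sweep(X, 2, object$reduction$center) %*% object$reduction$rotation
  }
  if (ncol(X) != object$p)
    stop("dimension mismatch: expected ", object$p, " variables, got ",
         ncol(X))
  g <- length(object$levels)
  disc <- matrix(0, nrow(X), g, dimnames = list(NULL, object$levels))
  for (j in seq_len(g)) {
    dev <- sweep(X, 2, object$means[j, ])
    z <- backsolve(object$chol, t(dev), transpose = TRUE)
    disc[, j] <- log(object$priors[j]) - 0.5 * colSums(z^2)
  }
  shift <- apply(disc, 1, max)
  post <- exp(disc - shift)
  post <- post / rowSums(post)
  cls <- factor(object$levels[apply(disc, 1, which.max)],
                levels = object$levels)
  list(class = cls, posterior = post)
}

#' Leave-one-out cross-validated confusion matrix
#'
#' For each specimen the discriminant model is refit from scratch on the
#' remaining n - 1 specimens and the held-out specimen is classified.
#' Superimposition and the rank-reduction basis are computed once on the
#' full dataset, not per fold, mirroring the study pipeline (one GPA, then
#' cross-validated LDA); the resulting leakage is negligible for shape data
#' but is documented, and callers wanting a stricter protocol can re-run the
#' whole pipeline per fold themselves.
#'
#' @param shapes `n x p` shape matrix
#' @param labels group labels at the rank of interest (species or genus)
#' @param priors `"proportional"` or `"uniform"`
#' @param rank free-text tag stored in the result (e.g. `"species"`)
#' @return object of class `confusion_matrix`: `counts` (true x predicted),
#'   `accuracy`, `rank`, `percentages` (row percentages)
#' @export
loocv_confusion <- function(shapes, labels,
                            priors = c("proportional", "uniform"),
                            rank = "species") {
  priors <- match.arg(priors)
  labels <- factor(labels)
  cnt <- table(labels)
  if (any(cnt < 2))
    stop("cannot hold out from group(s) of size 1: ",
         paste(names(cnt)[cnt < 2], collapse = ", "))
  # each fold drops one specimen, so keep the pooled covariance invertible
  # in the worst fold
  red <- reduce_rank(shapes, max_rank = nrow(as.matrix(shapes)) -
                       nlevels(labels) - 2L)
  X <- red$scores
  n <- nrow(X)
  pred <- character(n)
  for (i in seq_len(n)) {
    fit <- fit_lda(X[-i, , drop = FALSE], labels[-i], priors = priors,
                   reduce = FALSE)
    pred[i] <- as.character(predict(fit, X[i, , drop = FALSE])$class)
  }
  confusion_matrix(labels, factor(pred, levels = levels(labels)),
                   rank = rank)
}

#' Build a confusion matrix from true and predicted labels
#' @param true,predicted factors of equal length
#' @param rank free-text tag (e.g. `"species"`)
#' @return object of class `confusion_matrix`
#' @export
confusion_matrix <- function(true, predicted, rank = "") {
  lev <- union(levels(factor(true)), levels(factor(predicted)))
  true <- factor(true, levels = lev)
  predicted <- factor(predicted, levels = lev)
  counts <- table(true = true, predicted = predicted)
  acc <- sum(diag(counts)) / sum(counts)
  pct <- sweep(counts, 1, pmax(1, rowSums(counts)), "/") * 100
  structure(list(counts = unclass(counts), accuracy = acc, rank = rank,
                 percentages = unclass(pct)),
            class = "confusion_matrix")
}

#' @export
print.confusion_matrix <- function(x, digits = 1, ...) {
  cat("Leave-one-out reclassification",
      if (nzchar(x$rank)) paste0(" (", x$rank, ")"), ":\n", sep = "")
  cat(sprintf("Overall accuracy: %.1f%% (%d / %d)\n", 100 * x$accuracy,
              sum(diag(x$counts)), sum(x$counts)))
  cat("Row percentages (true x predicted):\n")
  print(round(x$percentages, digits))
  invisible(x)
}

#' Collapse a species-rank confusion matrix to genus rank
#'
#' Sums confusion counts within genus blocks. Misclassifications between
#' species of the same genus become correct at genus rank, so collapsing can
#' never decrease accuracy.
#'
#' @param species_confusion a `confusion_matrix` at species rank
#' @param genus_map named character vector, species label -> genus label
#' @return a `confusion_matrix` at genus rank
#' @export
collapse_to_genus <- function(species_confusion, genus_map) {
  stopifnot(inherits(species_confusion, "confusion_matrix"))
  cm <- species_confusion$counts
  sp <- rownames(cm)
  if (!all(sp %in% names(genus_map)))
    stop("genus_map does not cover species: ",
         paste(setdiff(sp, names(genus_map)), collapse = ", "))
  gen <- sort(unique(unname(genus_map[sp])))
  out <- matrix(0L, length(gen), length(gen), dimnames = list(gen, gen))
  for (i in sp) for (j in sp)
    out[genus_map[[i]], genus_map[[j]]] <-
      out[genus_map[[i]], genus_map[[j]]] + cm[i, j]
  acc <- sum(diag(out)) / sum(out)
  pct <- sweep(out, 1, pmax(1, rowSums(out)), "/") * 100
  structure(list(counts = out, accuracy = acc, rank = "genus (collapsed)",
                 percentages = pct),
            class = "confusion_matrix")
}

#' Canonical variate analysis with Mahalanobis distances
#'
#' Canonical axes maximize between-group relative to pooled within-group
#' variation (at most g - 1 axes for g groups); the Mahalanobis distance
#' matrix between group means, computed under the pooled within-group
#' covariance, feeds the neighbor-joining tree of species relationships in
#' shape space.
#'
#' @param shapes `n x p` shape matrix
#' @param labels group labels
#' @return object of class `cva_result`: `scores` (specimen scores on
#'   canonical axes), `axes` (column vectors in reduced space),
#'   `eigenvalues`, `mahalanobis` (g x g distance matrix), `labels`,
#'   `group_means`
#' @export
cva <- function(shapes, labels) {
  labels <- factor(labels)
  cnt <- table(labels)
  if (any(cnt < 2))
    stop("group(s) with a single specimen: ",
         paste(names(cnt)[cnt < 2], collapse = ", "))
  red <- reduce_rank(shapes,
                     max_rank = nrow(as.matrix(shapes)) - nlevels(labels) - 1L)
  X <- red$scores
  g <- nlevels(labels)
  # shrink the subspace until the pooled within-group covariance is well
  # conditioned (resampled data can carry duplicated specimens)
  r <- ncol(X)
  repeat {
    W_try <- pooled_within(X[, seq_len(r), drop = FALSE], labels)$cov
    ev <- eigen(W_try, symmetric = TRUE, only.values = TRUE)$values
    if (min(ev) > 1e-9 * max(ev) || r == 1) break
    r <- r - 1L
  }
  X <- X[, seq_len(r), drop = FALSE]
  n <- nrow(X)
  pw <- pooled_within(X, labels)
  W <- pw$cov
  mu <- colMeans(X)
  B <- matrix(0, ncol(X), ncol(X))
  for (gr in levels(labels)) {
    d <- pw$means[gr, ] - mu
    B <- B + as.numeric(cnt[gr]) * tcrossprod(d)
  }
  B <- B / (g - 1)
  eW <- eigen(W, symmetric = TRUE)
  if (min(eW$values) <= 0)
    stop("pooled within-group covariance is singular after reduction")
  Wih <- eW$vectors %*% diag(1 / sqrt(eW$values), ncol(X)) %*% t(eW$vectors)
  eM <- eigen(Wih %*% B %*% Wih, symmetric = TRUE)
  r <- min(g - 1, ncol(X))
  axes <- Wih %*% eM$vectors[, seq_len(r), drop = FALSE]
  scores <- sweep(X, 2, mu) %*% axes
  colnames(scores) <- paste0("CV", seq_len(r))
  # Mahalanobis distances between group means under W
  ch <- chol(W)
  Z <- t(backsolve(ch, t(pw$means), transpose = TRUE))
  D <- as.matrix(stats::dist(Z))
  dimnames(D) <- list(levels(labels), levels(labels))
  structure(list(scores = scores, axes = axes,
                 eigenvalues = pmax(0, eM$values[seq_len(r)]),
                 mahalanobis = D, labels = labels,
                 group_means = pw$means),
            class = "cva_result")
}

#' @export
print.cva_result <- function(x, ...) {
  cat("Canonical variate analysis: ", nlevels(x$labels), " groups, ",
      ncol(x$scores), " canonical axes\n", sep = "")
  cat("Leading eigenvalues: ",
      paste(sprintf("%.3g", utils::head(x$eigenvalues, 5)), collapse = ", "),
      "\n", sep = "")
  invisible(x)
}

#' @export
plot.cva_result <- function(x, axes = c(1, 2), ...) {
  s <- x$scores[, axes, drop = FALSE]
  cols <- as.integer(x$labels)
  graphics::plot(s, col = cols, pch = cols %% 25,
                 xlab = colnames(s)[1], ylab = colnames(s)[2],
                 main = "Canonical variate scores", ...)
  invisible(x)
}
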