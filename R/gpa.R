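#' Centroid size of a landmark configuration
#'
#' Centroid size (CS) is the square root of the summed squared distances
#' between each landmark and the configuration centroid. It is the standard
#' size measure of geometric morphometrics: the one size variable
#' uncorrelated with shape under isotropic landmark noise, and the quantity
#' removed (by rescaling to CS = 1) during Procrustes superimposition.
#'
#' @param config a `k x 2` coordinate matrix, or a [landmark_dataset()]
#'   (then a vector of per-specimen sizes is returned)
#' @return positive numeric; 0 only when all landmarks coincide
#' @examples
#' centroid_size(rbind(c(0, 0), c(1, 0), c(1, 1), c(0, 1)))  # sqrt(2)
#' @export
centroid_size <- function(config) {
  if (inherits(config, "landmark_dataset"))
    return(apply(config$coords, 3, centroid_size))
  config <- as.matrix(config)
  stopifnot(ncol(config) == 2, all(is.finite(config)))
  ctr <- colMeans(config)
  sqrt(sum((config[, 1] - ctr[1])^2 + (config[, 2] - ctr[2])^2))
}

center_config <- function(m) sweep(m, 2, colMeans(m))

# Optimal proper rotation (det +1) of centered target onto centered
# reference; closed form in 2-D from the cross/dot coordinate sums.
optimal_rotation_angle <- function(reference, target) {
  num <- sum(target[, 1] * reference[, 2] - target[, 2] * reference[, 1])
  den <- sum(target[, 1] * reference[, 1] + target[, 2] * reference[, 2])
  atan2(num, den)
}

rotate_config <- function(m, theta) {
  # counter-clockwise rotation of row-vector coordinates by theta
  R <- matrix(c(cos(theta), -sin(theta), sin(theta), cos(theta)), 2, 2)
  m %*% R
}

# Rotation angle taking a centered configuration to its canonical frame:
# first principal axis along x, third moment of x positive. NA when the
# configuration is rotationally degenerate (near-isotropic).
canonical_angle <- function(m) {
  cc <- crossprod(m) / nrow(m)
  ev <- eigen(cc, symmetric = TRUE)
  if (ev$values[1] - ev$values[2] < 1e-12 * max(ev$values[1], 1e-300))
    return(NA_real_)
  v1 <- ev$vectors[, 1]
  th <- -atan2(v1[2], v1[1])
  r <- rotate_config(m, th)
  s <- sum(r[, 1]^3)
  if (abs(s) < 1e-12) s <- sum(r[, 1] * r[, 2]^2)
  if (s < 0) th <- th + pi
  th
}

#' Ordinary Procrustes alignment of one configuration onto another
#'
#' Finds the similarity transform (translation, proper rotation and, when
#' `scale = TRUE`, isotropic scaling -- never a reflection) of `target`
#' minimizing the root summed squared landmark distance to `reference`.
#' With `scale = TRUE` both shapes are pre-scaled to unit centroid size and
#' the reported distance is the (partial) Procrustes distance between the
#' two shapes.
#'
#' @param reference,target `k x 2` coordinate matrices with the same `k`
#' @param scale remove size before rotation? (default `TRUE`)
#' @return list with `aligned` (transformed target), `angle` (radians,
#'   counter-clockwise), `scale` (factor applied to the centered target),
#'   `distance` (the minimized root-sum-of-squares)
#' @export
align_pair <- function(reference, target, scale = TRUE) {
  reference <- as.matrix(reference); target <- as.matrix(target)
  if (!all(dim(reference) == dim(target)) || ncol(reference) != 2)
    stop("reference and target must be k x 2 matrices with equal k")
  cs_r <- centroid_size(reference); cs_t <- centroid_size(target)
  if (cs_r <= 0 || cs_t <= 0)
    stop("degenerate configuration: zero centroid size")
  ref_c <- center_config(reference); tar_c <- center_config(target)
  if (scale) {
    ref_c <- ref_c / cs_r
    s <- 1 / cs_t
  } else {
    s <- 1
  }
  tar_s <- tar_c * s
  theta <- optimal_rotation_angle(ref_c, tar_s)
  aligned <- rotate_config(tar_s, theta)
  d <- sqrt(sum((aligned - ref_c)^2))
  aligned <- sweep(aligned, 2, colMeans(reference), "+")
  list(aligned = aligned, angle = theta, scale = s, distance = d)
}

#' Generalized Procrustes analysis
#'
#' Iterative superimposition of all configurations in a dataset: each
#' configuration is centered and rescaled to unit centroid size, rotated
#' onto a provisional consensus, and the consensus (the arithmetic mean
#' shape, itself rescaled to unit centroid size) is recomputed until it
#' stabilizes. Rotations are restricted to determinant +1: with wings of a
#' single side, chirality is fixed and reflections would be anatomical
#' nonsense. The original centroid sizes are retained so size can be
#' analysed separately from shape.
#'
#' @param dataset a [landmark_dataset()] with at least 2 configurations
#' @param tol convergence tolerance on the root summed squared change of the
#'   consensus between iterations
#' @param max_iter iteration cap; non-convergence yields a warning and
#'   `converged = FALSE`, never an error
#' @return object of class `wing_gpa`: `coords` (k x 2 x n aligned
#'   Procrustes coordinates, unit centroid size each), `centroid_sizes`
#'   (original units), `consensus` (k x 2, unit centroid size), `converged`,
#'   `iterations`, `meta`, `k`, `tol`
#' @export
generalized_procrustes <- function(dataset, tol = 1e-8, max_iter = 100) {
  stopifnot(inherits(dataset, "landmark_dataset"))
  n <- n_specimens(dataset)
  if (n < 2) stop("GPA needs at least 2 configurations")
  k <- dataset$k
  cs <- centroid_size(dataset)
  if (any(cs <= 0))
    stop("degenerate configuration (zero centroid size): specimen ",
         dataset$meta$specimen[which(cs <= 0)[1]])
  aligned <- array(0, dim = c(k, 2, n), dimnames = dimnames(dataset$coords))
  for (i in seq_len(n))
    aligned[, , i] <- center_config(dataset$coords[, , i]) / cs[i]
  consensus <- aligned[, , 1]
  converged <- FALSE
  iter <- 0L
  while (iter < max_iter) {
    iter <- iter + 1L
    for (i in seq_len(n)) {
      th <- optimal_rotation_angle(consensus, aligned[, , i])
      aligned[, , i] <- rotate_config(aligned[, , i], th)
    }
    new_cons <- apply(aligned, c(1, 2), mean)
    new_cons <- center_config(new_cons)
    new_cons <- new_cons / centroid_size(new_cons)
    delta <- sqrt(sum((new_cons - consensus)^2))
    consensus <- new_cons
    if (delta < tol) { converged <- TRUE; break }
  }
  if (!converged)
    warning("GPA did not converge in ", max_iter, " iterations")
  # canonical orientation: principal axis of the consensus along x, with the
  # x-skew sign fixed, so the solution does not depend on the (arbitrary)
  # orientation of the input configurations
  th <- canonical_angle(consensus)
  if (!is.na(th)) {
    consensus <- rotate_config(consensus, th)
    for (i in seq_len(n)) aligned[, , i] <- rotate_config(aligned[, , i], th)
  }
  structure(list(coords = aligned, centroid_sizes = cs, consensus = consensus,
                 converged = converged, iterations = iter, meta = dataset$meta,
                 k = k, tol = tol),
            class = "wing_gpa")
}

#' @export
print.wing_gpa <- function(x, ...) {
  cat("Generalized Procrustes superimposition\n")
  cat("  ", dim(x$coords)[3], " specimens x ", x$k, " landmarks; ",
      x$iterations, " iteration(s), ",
      if (x$converged) "converged" else "NOT converged",
      " (tol ", format(x$tol), ")\n", sep = "")
  cat("  centroid size: ", sprintf("%.4g - %.4g (median %.4g)",
      min(x$centroid_sizes), max(x$centroid_sizes),
      stats::median(x$centroid_sizes)), "\n", sep = "")
  invisible(x)
}

#' @export
plot.wing_gpa <- function(x, ...) {
  n <- dim(x$coords)[3]
  xs <- as.vector(x$coords[, 1, ]); ys <- as.vector(x$coords[, 2, ])
  graphics::plot(xs, ys, pch = ".", col = "grey50", asp = 1,
                 xlab = "x (Procrustes units)", ylab = "y (Procrustes units)",
                 main = "Superimposed landmarks", ...)
  graphics::points(x$consensus, pch = 19, col = "red")
  invisible(x)
}

#' Tangent-space shape variables
#'
#' Projects the aligned coordinates orthogonally onto the linear tangent
#' plane to shape space at the consensus (the plane through the consensus
#' orthogonal to it, in the 2k-dimensional coordinate space). Because
#' within-sample Procrustes distances are small, the projection moves points
#' by a negligible amount, but it makes ordinary linear multivariate
#' statistics exactly valid. Rows are specimens, columns are
#' `x1, y1, ..., xk, yk`.
#'
#' @param aligned a `wing_gpa` object
#' @param project if `FALSE`, return the raw aligned coordinates as rows
#'   without tangent projection (for sensitivity analyses)
#' @return numeric matrix `n x 2k` with class attribute `shape_matrix`;
#'   attribute `consensus` holds the vectorized consensus
#' @export
tangent_projection <- function(aligned, project = TRUE) {
  stopifnot(inherits(aligned, "wing_gpa"))
  n <- dim(aligned$coords)[3]; k <- aligned$k
  X <- t(apply(aligned$coords, 3, function(m) as.vector(t(m))))
  cvec <- as.vector(t(aligned$consensus))  # unit norm: consensus has CS 1
  if (project) {
    # orthogonal projection onto the affine plane { y : <y, c> = <c, c> }
    X <- X + outer(1 - as.vector(X %*% cvec), cvec)
  }
  colnames(X) <- as.vector(rbind(paste0("x", 1:k), paste0("y", 1:k)))
  rownames(X) <- aligned$meta$specimen
  attr(X, "consensus") <- cvec
  attr(X, "projected") <- project
  class(X) <- c("shape_matrix", class(X))
  X
}

#' Mean shape of a group of aligned specimens
#'
#' Arithmetic mean of the aligned coordinates of the selected specimens,
#' re-centered and rescaled to unit centroid size; used to visualize shape
#' differences between taxa by overlaying group means.
#'
#' @param aligned a `wing_gpa` object
#' @param select logical/integer specimen index, or a character label matched
#'   against species then genus metadata; `NULL` selects all specimens
#' @return `k x 2` matrix with unit centroid size
#' @export
mean_shape <- function(aligned, select = NULL) {
  stopifnot(inherits(aligned, "wing_gpa"))
  n <- dim(aligned$coords)[3]
  idx <- if (is.null(select)) seq_len(n)
    else if (is.character(select))
      which(aligned$meta$species %in% select | aligned$meta$genus %in% select)
    else if (is.logical(select)) which(select)
    else as.integer(select)
  if (!length(idx)) stop("empty selection in mean_shape()")
  m <- apply(aligned$coords[, , idx, drop = FALSE], c(1, 2), mean)
  m <- center_config(m)
  m / centroid_size(m)
}

#' Pairwise Procrustes distance matrix between specimens
#' @param aligned a `wing_gpa` object
#' @param tangent use tangent-space Euclidean distances (default) rather
#'   than exact pairwise ordinary-Procrustes distances
#' @return `n x n` symmetric distance matrix
#' @export
procrustes_distances <- function(aligned, tangent = TRUE) {
  if (tangent) {
    X <- tangent_projection(aligned)
    return(as.matrix(stats::dist(X)))
  }
  n <- dim(aligned$coords)[3]
  d <- matrix(0, n, n)
  for (i in seq_len(n - 1)) for (j in (i + 1):n) {
    d[i, j] <- align_pair(aligned$coords[, , i],
                          aligned$coords[, , j])$distance
    d[j, i] <- d[i, j]
  }
  d
}
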