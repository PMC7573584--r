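#' Landmark sampling evaluation curve (LaSEC)
#'
#' Diagnoses whether a landmark scheme under- or over-samples shape
#' information. In each iteration a random ordering of the landmarks is
#' drawn and nested subsets of size 3, 4, ..., k are taken; for each subset
#' the specimens are re-superimposed on the subset alone and the fidelity of
#' the subsampled shape space to the full shape space is computed as the
#' Pearson correlation between the vectorized lower triangles of the
#' inter-specimen tangent-space distance matrices. A curve that saturates
#' well before size k indicates redundant landmarks; a curve still rising at
#' k indicates undersampling. The subset of size k is the full scheme, so
#' its fit is 1 by construction.
#'
#' Subsets whose superimposition degenerates (e.g. a collinear 3-landmark
#' draw with zero shape variance) cause the whole iteration to be redrawn;
#' the number of redraws is reported.
#'
#' @param dataset a [landmark_dataset()] with k >= 4 landmarks and >= 3
#'   specimens
#' @param n_iterations random sampling iterations (default 1000)
#' @param seed optional integer seed
#' @return object of class `lasec_curve`: `curve` (data frame with columns
#'   `size`, `median_fit`, `p05`, `p95`), `n_iterations`, `seed`,
#'   `n_resampled`, `fits` (iterations x sizes matrix)
#' @export
lasec_curve <- function(dataset, n_iterations = 1000, seed = NULL) {
  stopifnot(inherits(dataset, "landmark_dataset"))
  k <- dataset$k
  if (k < 4) stop("LaSEC needs at least 4 landmarks")
  n <- n_specimens(dataset)
  if (n < 3) stop("LaSEC needs at least 3 specimens")
  full <- generalized_procrustes(dataset)
  full_d <- stats::dist(tangent_projection(full))
  sizes <- 3:k
  fit_for_subset <- function(sub) {
    d <- landmark_dataset(dataset$coords[sub, , , drop = FALSE], dataset$meta)
    g <- suppressWarnings(generalized_procrustes(d))
    dd <- stats::dist(tangent_projection(g))
    if (stats::sd(dd) == 0 || stats::sd(full_d) == 0) return(NA_real_)
    stats::cor(as.vector(dd), as.vector(full_d))
  }
  n_resampled <- 0L
  fits <- with_seed(seed, {
    out <- matrix(NA_real_, n_iterations, length(sizes))
    for (it in seq_len(n_iterations)) {
      repeat {
        perm <- sample.int(k)
        row <- rep(NA_real_, length(sizes))
        ok <- TRUE
        for (si in seq_along(sizes)) {
          s <- sizes[si]
          if (s == k) { row[si] <- 1; next }
          f <- tryCatch(fit_for_subset(sort(perm[1:s])),
                        error = function(e) NA_real_)
          if (is.na(f)) { ok <- FALSE; break }
          row[si] <- f
        }
        if (ok) { out[it, ] <- row; break }
        n_resampled <- n_resampled + 1L
        if (n_resampled > 100L * n_iterations)
          stop("LaSEC: too many degenerate landmark subsets")
      }
    }
    out
  })
  curve <- data.frame(
    size = sizes,
    median_fit = apply(fits, 2, stats::median),
    p05 = apply(fits, 2, stats::quantile, probs = 0.05),
    p95 = apply(fits, 2, stats::quantile, probs = 0.95))
  structure(list(curve = curve, n_iterations = n_iterations, seed = seed,
                 n_resampled = n_resampled, fits = fits),
            class = "lasec_curve")
}

#' @export
print.lasec_curve <- function(x, ...) {
  cat("Landmark sampling evaluation curve (", x$n_iterations,
      " iterations)\n", sep = "")
  print(round(x$curve, 4), row.names = FALSE)
  if (x$n_resampled > 0)
    cat(x$n_resampled, "iteration(s) redrawn for degenerate subsets\n")
  invisible(x)
}

#' @export
plot.lasec_curve <- function(x, ...) {
  cv <- x$curve
  graphics::plot(cv$size, cv$median_fit, type = "b", pch = 19,
                 ylim = range(c(cv$p05, cv$p95, 1)),
                 xlab = "number of landmarks sampled", ylab = "fit",
                 main = "Landmark sampling evaluation curve", ...)
  graphics::lines(cv$size, cv$p05, lty = 2)
  graphics::lines(cv$size, cv$p95, lty = 2)
  invisible(x)
}
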