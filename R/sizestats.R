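# Run expr with a temporarily seeded RNG, restoring the caller's RNG state.
with_seed <- function(seed, expr) {
  if (is.null(seed)) return(expr)
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  expr
}

#' One-way ANOVA of centroid size across species
#'
#' Fixed-effects one-way analysis of variance of per-specimen centroid size
#' by group label, the standard first look at interspecific size differences.
#'
#' @param sizes positive numeric vector of centroid sizes
#' @param labels group (species) labels, same length
#' @return list with `f_statistic`, `df_between`, `df_within`, `p_value`
#' @export
anova_centroid_size <- function(sizes, labels) {
  labels <- factor(labels)
  if (nlevels(labels) < 2) stop("need at least 2 groups")
  cnt <- table(labels)
  if (any(cnt < 2))
    stop("every group needs >= 2 specimens; offending: ",
         paste(names(cnt)[cnt < 2], collapse = ", "))
  fit <- stats::lm(sizes ~ labels)
  an <- stats::anova(fit)
  if (!is.finite(an[1, "F value"]))
    stop("F undefined: zero pooled within-group variance")
  list(f_statistic = an[1, "F value"],
       df_between = an[1, "Df"], df_within = an[2, "Df"],
       p_value = an[1, "Pr(>F)"])
}

#' Pairwise t-tests with Bonferroni correction
#'
#' All g(g-1)/2 two-sample pooled-variance t-tests between group centroid
#' sizes, with the Bonferroni adjustment `p_adj = min(1, m * p_raw)` over the
#' m comparisons.
#'
#' @inheritParams anova_centroid_size
#' @return symmetric `g x g` matrix of adjusted p-values, diagonal 1
#' @export
pairwise_t_bonferroni <- function(sizes, labels) {
  labels <- factor(labels)
  g <- nlevels(labels)
  if (g < 2) stop("need at least 2 groups")
  cnt <- table(labels)
  if (any(cnt < 2))
    stop("every group needs >= 2 specimens; offending: ",
         paste(names(cnt)[cnt < 2], collapse = ", "))
  lev <- levels(labels)
  raw <- numeric(0); ii <- integer(0); jj <- integer(0)
  for (i in seq_len(g - 1)) for (j in (i + 1):g) {
    raw <- c(raw, stats::t.test(sizes[labels == lev[i]],
                                sizes[labels == lev[j]],
                                var.equal = TRUE)$p.value)
    ii <- c(ii, i); jj <- c(jj, j)
  }
  padj <- stats::p.adjust(raw, method = "bonferroni")  # min(1, m * p)
  adj <- matrix(1, g, g, dimnames = list(lev, lev))
  adj[cbind(ii, jj)] <- padj
  adj[cbind(jj, ii)] <- padj
  adj
}

#' Permutation test for allometry (shape on log centroid size)
#'
#' Multivariate regression of the tangent-space shape variables on
#' log centroid size. The effect size is R^2 = SS_model / SS_total summed
#' over all shape columns; significance comes from randomly permuting the
#' specimen-to-size assignment and recomputing the pseudo-F, so no
#' distributional assumption on the (highly collinear) shape variables is
#' needed. The permutation p-value uses the add-one convention
#' `p = (1 + #{F_perm >= F_obs}) / (1 + n_permutations)`, whose smallest
#' attainable value at 500 permutations is 1/501 ~ 0.002.
#'
#' @param shapes `n x p` shape matrix (see [tangent_projection()])
#' @param sizes positive centroid sizes, length n
#' @param n_permutations number of random permutations (default 500)
#' @param seed optional integer seed for the permutation stream
#' @return object of class `allometry_result`: `r_squared`, `f_statistic`,
#'   `p_value`, `n_permutations`, `seed`
#' @export
allometry_test <- function(shapes, sizes, n_permutations = 500, seed = NULL) {
  shapes <- as.matrix(shapes)
  n <- nrow(shapes)
  stopifnot(length(sizes) == n, n_permutations >= 1)
  x <- log(sizes)
  x <- x - mean(x)
  if (sum(x^2) == 0) stop("constant centroid sizes: regressor degenerate")
  Y <- sweep(shapes, 2, colMeans(shapes))
  ss_total <- sum(Y^2)
  if (ss_total == 0) stop("zero total shape variation")
  xx <- sum(x^2)
  f_of <- function(xv) {
    ss_m <- sum(as.vector(crossprod(Y, xv))^2) / xx
    (ss_m / 1) / ((ss_total - ss_m) / (n - 2))
  }
  ss_model <- sum(as.vector(crossprod(Y, x))^2) / xx
  r2 <- ss_model / ss_total
  f_obs <- (ss_model / 1) / ((ss_total - ss_model) / (n - 2))
  P <- with_seed(seed,
    vapply(seq_len(n_permutations), function(b) sample(x), numeric(n)))
  M <- crossprod(Y, P)                       # p x B
  ss_perm <- colSums(M^2) / xx
  f_perm <- ss_perm / ((ss_total - ss_perm) / (n - 2))
  p <- (1 + sum(f_perm >= f_obs)) / (1 + n_permutations)
  structure(list(r_squared = r2, f_statistic = f_obs, p_value = p,
                 n_permutations = n_permutations, seed = seed),
            class = "allometry_result")
}

#' @export
print.allometry_result <- function(x, ...) {
  cat(sprintf(
    "Allometry (shape ~ log CS): R2 = %.3f%%, F = %.3f, p = %.4g (%d permutations)\n",
    100 * x$r_squared, x$f_statistic, x$p_value, x$n_permutations))
  invisible(x)
}

#' Procrustes shape variance (disparity) per group
#'
#' Procrustes variance of a group is the mean squared distance of its
#' members' shape variables to the group mean -- the morphometric analogue
#' of a trace of a covariance matrix, used both for species-level shape
#' variation and for observer measurement error. The denominator is n
#' (the convention of the morphometrics software family this mirrors);
#' set `unbiased = TRUE` for n - 1.
#'
#' @param shapes a `wing_gpa` object or an `n x p` shape matrix
#' @param labels group labels, length n
#' @param unbiased divide by n - 1 instead of n
#' @return object of class `disparity_result`: `per_group_variance` (named
#'   numeric), `grand_mean_variance`, `excluded` (singleton groups)
#' @export
shape_variance <- function(shapes, labels, unbiased = FALSE) {
  if (inherits(shapes, "wing_gpa")) shapes <- tangent_projection(shapes)
  shapes <- as.matrix(shapes)
  stopifnot(nrow(shapes) == length(labels))
  labels <- as.character(labels)
  cnt <- table(labels)
  singletons <- names(cnt)[cnt < 2]
  if (length(singletons))
    warning("singleton group(s) excluded from disparity: ",
            paste(singletons, collapse = ", "))
  keep <- setdiff(names(cnt), singletons)
  v <- vapply(keep, function(g) {
    M <- shapes[labels == g, , drop = FALSE]
    dev <- sweep(M, 2, colMeans(M))
    sum(dev^2) / (nrow(M) - if (unbiased) 1 else 0)
  }, numeric(1))
  structure(list(per_group_variance = v, grand_mean_variance = mean(v),
                 excluded = singletons, unbiased = unbiased),
            class = "disparity_result")
}

#' @export
print.disparity_result <- function(x, ...) {
  cat("Procrustes shape variance per group:\n")
  print(round(x$per_group_variance, 6))
  cat(sprintf("Grand mean variance: %.6g\n", x$grand_mean_variance))
  invisible(x)
}

# Concatenate two landmark datasets (same k, compatible metadata).
combine_datasets <- function(a, b) {
  stopifnot(inherits(a, "landmark_dataset"), inherits(b, "landmark_dataset"),
            a$k == b$k)
  coords <- array(c(a$coords, b$coords), dim = c(a$k, 2, n_specimens(a) +
                                                   n_specimens(b)))
  landmark_dataset(coords, rbind(a$meta, b$meta))
}

#' Observer (digitization) error report
#'
#' Quantifies how much of the measured shape variation is digitization noise
#' rather than biology. All configurations -- originals plus the repeated
#' measurements by several observers -- are superimposed jointly; the mean
#' per-specimen Procrustes variance across a specimen's observer replicates
#' is then compared with the mean per-species variance of the original
#' (non-replicate) specimens. A ratio well below 1 indicates that observer
#' error is small relative to the species-level signal the classifier uses.
#'
#' @param original a [landmark_dataset()] of single measurements
#' @param replicates a [landmark_dataset()] of repeated measurements of a
#'   subset of specimens, with `observer` metadata set and the `specimen`
#'   ids matching `original`
#' @return object of class `observer_error_report`: `observer_variance`
#'   (mean per-specimen variance over observers), `species_variance` (mean
#'   per-species variance of originals), `ratio`, `n_repeated_specimens`,
#'   `per_specimen_variance`
#' @export
observer_error_report <- function(original, replicates) {
  stopifnot(inherits(original, "landmark_dataset"),
            inherits(replicates, "landmark_dataset"))
  rep_meta <- replicates$meta
  if (length(unique(rep_meta$observer[nzchar(rep_meta$observer)])) < 2)
    stop("replicates must carry >= 2 distinct observer ids")
  combined <- combine_datasets(original, replicates)
  gpa <- generalized_procrustes(combined)
  shapes <- tangent_projection(gpa)
  n_orig <- n_specimens(original)
  is_rep <- c(rep(FALSE, n_orig), rep(TRUE, n_specimens(replicates)))
  meta <- combined$meta
  rep_ids <- unique(meta$specimen[is_rep])
  per_spec <- vapply(rep_ids, function(id) {
    M <- shapes[is_rep & meta$specimen == id, , drop = FALSE]
    if (nrow(M) < 2) return(NA_real_)
    dev <- sweep(M, 2, colMeans(M))
    sum(dev^2) / nrow(M)
  }, numeric(1))
  per_spec <- per_spec[!is.na(per_spec)]
  if (!length(per_spec)) stop("no specimen has >= 2 observer replicates")
  sp_var <- shape_variance(shapes[!is_rep, , drop = FALSE],
                           meta$species[!is_rep])
  obs_v <- mean(per_spec)
  structure(list(observer_variance = obs_v,
                 species_variance = sp_var$grand_mean_variance,
                 ratio = obs_v / sp_var$grand_mean_variance,
                 n_repeated_specimens = length(per_spec),
                 per_specimen_variance = per_spec,
                 per_species_variance = sp_var$per_group_variance),
            class = "observer_error_report")
}

#' @export
print.observer_error_report <- function(x, ...) {
  cat(sprintf(
    "Observer error: mean per-specimen variance %.5g over %d repeated specimens\n",
    x$observer_variance, x$n_repeated_specimens))
  cat(sprintf("Mean per-species variance (originals): %.5g\n",
              x$species_variance))
  cat(sprintf("Ratio observer/species: %.3f\n", x$ratio))
  invisible(x)
}
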