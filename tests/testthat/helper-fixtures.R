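# Shared fixtures and small oracles, all built in code.

rot_mat <- function(th) matrix(c(cos(th), -sin(th), sin(th), cos(th)), 2, 2)

# random similarity transform of a k x 2 configuration
similarity_transform <- function(m, angle = stats::runif(1, 0, 2 * pi),
                                 scale = stats::runif(1, 0.5, 2),
                                 shift = stats::runif(2, -5, 5)) {
  sweep((m %*% rot_mat(angle)) * scale, 2, shift, "+")
}

# tiny multi-species dataset for quick pipeline checks
small_design <- function(n_per_species = 8, n_sites = 2, ...) {
  simulation_design(species = paste0("sp", 1:4),
                    genus_map = stats::setNames(c("gA", "gA", "gB", "gB"),
                                                paste0("sp", 1:4)),
                    n_per_species = n_per_species, n_sites = n_sites, ...)
}

# brute-force LDA rule: explicit covariance inverse and Mahalanobis loop
oracle_lda_predict <- function(Xtr, labels, Xte, priors_type = "proportional") {
  labels <- factor(labels)
  lev <- levels(labels)
  n <- nrow(Xtr)
  means <- t(sapply(lev, function(g) colMeans(Xtr[labels == g, , drop = FALSE])))
  W <- matrix(0, ncol(Xtr), ncol(Xtr))
  for (g in lev) {
    M <- Xtr[labels == g, , drop = FALSE]
    dev <- sweep(M, 2, colMeans(M))
    W <- W + t(dev) %*% dev
  }
  W <- W / (n - length(lev))
  Winv <- solve(W)
  pr <- if (priors_type == "proportional")
    as.numeric(table(labels)) / n else rep(1 / length(lev), length(lev))
  apply(Xte, 1, function(x) {
    sc <- sapply(seq_along(lev), function(j) {
      d <- x - means[j, ]
      log(pr[j]) - 0.5 * drop(t(d) %*% Winv %*% d)
    })
    lev[which.max(sc)]
  })
}

# grid search over rotation angle for the ordinary Procrustes distance
oracle_procrustes_distance <- function(a, b, step = 1e-4) {
  ctr <- function(m) sweep(m, 2, colMeans(m))
  cs <- function(m) sqrt(sum(ctr(m)^2))
  a <- ctr(a) / cs(a); b <- ctr(b) / cs(b)
  th <- seq(-pi, pi, by = step)
  min(vapply(th, function(t) sqrt(sum((b %*% rot_mat(t) - a)^2)), numeric(1)))
}

# exhaustive site-likelihood enumeration for a 4-taxon unrooted tree
# ((t1,t2)u,(t3,t4)v) with internal edge u-v; no rate variation
oracle_4taxon_loglik <- function(aln, model, bl) {
  # bl: named lengths t1..t4 and internal
  P <- lapply(bl, function(t) transition_probability(model, t))
  base_idx <- function(ch) match(ch, c("A", "C", "G", "T"))
  total <- 0
  for (s in seq_len(ncol(aln))) {
    obs <- base_idx(aln[c("t1", "t2", "t3", "t4"), s])
    lik <- 0
    for (u in 1:4) for (v in 1:4) {
      lik <- lik + model$pi[u] *
        P$t1[u, obs[1]] * P$t2[u, obs[2]] *
        P$internal[u, v] *
        P$t3[v, obs[3]] * P$t4[v, obs[4]]
    }
    total <- total + log(unname(lik))
  }
  total
}
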