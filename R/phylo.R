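#' Nucleotide substitution model (JC69 / K80 / HKY85, optional +Gamma)
#'
#' Time-reversible substitution models on {A, C, G, T}: JC69 (equal rates,
#' equal frequencies), K80 (transition/transversion ratio kappa, equal
#' frequencies) and HKY85 (kappa plus arbitrary base frequencies). The rate
#' matrix is scaled to one expected substitution per unit branch length.
#' Among-site rate variation is the discrete-Gamma approximation with
#' `n_categories` equal-probability categories whose rates are the means of
#' the quantile bins of Gamma(alpha, alpha) (so the category rates average
#' exactly 1 for any alpha).
#'
#' @param family `"JC69"`, `"K80"` or `"HKY85"`
#' @param kappa transition/transversion rate ratio (fixed at 1 for JC69)
#' @param base_freq length-4 frequencies in A, C, G, T order; default equal
#'   (forced equal for JC69/K80)
#' @param gamma enable Gamma rate variation
#' @param alpha Gamma shape (> 0); ignored when `gamma = FALSE`
#' @param n_categories discrete Gamma categories (default 4)
#' @return object of class `substitution_model` with the scaled rate matrix
#'   `Q`, its spectral decomposition, and the category rates
#' @export
substitution_model <- function(family = c("HKY85", "JC69", "K80"),
                               kappa = 1, base_freq = NULL,
                               gamma = FALSE, alpha = 1, n_categories = 4) {
  family <- match.arg(family)
  if (family %in% c("JC69", "K80")) base_freq <- rep(0.25, 4)
  if (family == "JC69") kappa <- 1
  if (is.null(base_freq)) base_freq <- rep(0.25, 4)
  stopifnot(length(base_freq) == 4, all(base_freq > 0), kappa >= 0,
            alpha > 0, n_categories >= 1)
  pi <- base_freq / sum(base_freq)
  names(pi) <- c("A", "C", "G", "T")
  # transitions: A<->G, C<->T
  rate <- matrix(1, 4, 4, dimnames = list(names(pi), names(pi)))
  rate["A", "G"] <- rate["G", "A"] <- kappa
  rate["C", "T"] <- rate["T", "C"] <- kappa
  Q <- rate * rep(pi, each = 4)        # q_ij = rate_ij * pi_j
  diag(Q) <- 0
  diag(Q) <- -rowSums(Q)
  mu <- -sum(pi * diag(Q))             # expected rate
  Q <- Q / mu
  # spectral decomposition via the pi-symmetrized matrix
  sq <- sqrt(pi)
  S <- diag(sq) %*% Q %*% diag(1 / sq)
  es <- eigen((S + t(S)) / 2, symmetric = TRUE)
  U <- diag(1 / sq) %*% es$vectors
  V <- t(es$vectors) %*% diag(sq)
  rates <- if (gamma) gamma_category_rates(alpha, n_categories) else 1
  structure(list(family = family, kappa = kappa, pi = pi, gamma = gamma,
                 alpha = alpha, n_categories = if (gamma) n_categories else 1L,
                 Q = Q, eigenvalues = es$values, U = U, V = V,
                 category_rates = rates),
            class = "substitution_model")
}

#' @export
print.substitution_model <- function(x, ...) {
  cat(x$family, if (x$gamma) "+G", " model: kappa = ", format(x$kappa),
      if (x$gamma) paste0(", alpha = ", format(x$alpha), " (",
                          x$n_categories, " categories)"),
      "\n", sep = "")
  cat("base frequencies: ",
      paste(sprintf("%s=%.3f", names(x$pi), x$pi), collapse = " "), "\n")
  invisible(x)
}

#' Discrete Gamma category rates (mean-of-bin variant)
#' @param alpha Gamma shape
#' @param n_categories number of equal-probability categories
#' @return numeric rates averaging exactly 1
#' @export
gamma_category_rates <- function(alpha, n_categories = 4) {
  q <- stats::qgamma(seq(0, 1, length.out = n_categories + 1),
                     shape = alpha, rate = alpha)
  p <- stats::pgamma(q, shape = alpha + 1, rate = alpha)
  n_categories * diff(p)
}

#' Transition probability matrix P(t) = exp(Qt)
#' @param model a `substitution_model`
#' @param t branch length (expected substitutions per site), >= 0
#' @return 4 x 4 row-stochastic matrix
#' @export
transition_probability <- function(model, t) {
  P <- model$U %*% (exp(model$eigenvalues * t) * model$V)
  P[P < 0] <- 0
  P / rowSums(P)
}

# -- alignment helpers --------------------------------------------------------

ambiguous_chars <- c("-", "N", "?", ".")

check_alignment <- function(aln) {
  aln <- as.matrix(aln)
  if (is.null(rownames(aln))) stop("alignment rows must be named by taxon")
  if (anyDuplicated(rownames(aln))) stop("duplicate taxon labels")
  aln[] <- toupper(aln)
  bad <- setdiff(unique(as.vector(aln)), c("A", "C", "G", "T",
                                           ambiguous_chars))
  if (length(bad)) stop("unsupported alignment characters: ",
                        paste(bad, collapse = " "))
  aln
}

#' Trim an alignment to its first target_length columns
#' @param aln character matrix (taxa x sites)
#' @param target_length number of leading columns to keep (default 550 bp,
#'   the trimmed COI fragment length used for barcoding here)
#' @return trimmed alignment
#' @export
trim_alignment <- function(aln, target_length = 550) {
  aln <- check_alignment(aln)
  if (ncol(aln) < target_length)
    stop("alignment has ", ncol(aln), " columns, shorter than target ",
         target_length, " (", target_length - ncol(aln), " bp short)")
  aln[, seq_len(target_length), drop = FALSE]
}

#' Read / write aligned FASTA
#' @param path FASTA file of equal-length sequences
#' @return character matrix (taxa x sites), uppercase
#' @export
read_fasta_alignment <- function(path) {
  d <- ape::read.FASTA(path)
  m <- as.character(as.matrix(d))
  m[] <- toupper(m)
  check_alignment(m)
}

#' @rdname read_fasta_alignment
#' @param aln character matrix (taxa x sites)
#' @param path file path
#' @export
write_fasta_alignment <- function(aln, path) {
  aln <- check_alignment(aln)
  out <- character(0)
  for (i in seq_len(nrow(aln)))
    out <- c(out, paste0(">", rownames(aln)[i]),
             paste(aln[i, ], collapse = ""))
  writeLines(out, path)
  invisible(path)
}

#' Empirical base frequencies of an alignment
#' @param aln character matrix
#' @return length-4 frequencies (A, C, G, T), gaps and Ns ignored
#' @export
empirical_base_freq <- function(aln) {
  aln <- check_alignment(aln)
  cnt <- vapply(c("A", "C", "G", "T"), function(b) sum(aln == b), numeric(1))
  if (any(cnt == 0)) cnt <- cnt + 1  # guard against absent bases
  cnt / sum(cnt)
}

# Compress an alignment into site patterns with weights; tip conditional
# likelihood matrices (4 x n_patterns) per taxon.
compress_patterns <- function(aln) {
  aln <- check_alignment(aln)
  key <- apply(aln, 2, paste, collapse = "\r")
  first <- !duplicated(key)
  weights <- as.vector(table(factor(key, levels = key[first])))
  pat <- aln[, first, drop = FALSE]
  statevec <- function(ch) switch(ch,
    A = c(1, 0, 0, 0), C = c(0, 1, 0, 0),
    G = c(0, 0, 1, 0), T = c(0, 0, 0, 1), c(1, 1, 1, 1))
  tips <- lapply(rownames(aln), function(tx)
    vapply(pat[tx, ], statevec, numeric(4)))
  names(tips) <- rownames(aln)
  list(tips = tips, weights = weights, n_patterns = ncol(pat),
       n_sites = ncol(aln), taxa = rownames(aln))
}

col_max <- function(m) {
  if (nrow(m) == 4L) pmax.int(m[1L, ], m[2L, ], m[3L, ], m[4L, ])
  else do.call(pmax.int, lapply(seq_len(nrow(m)), function(i) m[i, ]))
}

log_sum_exp <- function(m) {
  # rows = categories, cols = patterns; returns per-column logsumexp
  mx <- col_max(m)
  mx + log(colSums(exp(sweep(m, 2, mx))))
}

# Postorder scaffolding shared by the likelihood routines.
tree_postorder <- function(tree, taxa) {
  if (!setequal(tree$tip.label, taxa))
    stop("tree tips and alignment taxa differ: ",
         paste(union(setdiff(tree$tip.label, taxa),
                     setdiff(taxa, tree$tip.label)), collapse = ", "))
  po <- ape::reorder.phylo(tree, "postorder")
  list(po = po, n = length(po$tip.label),
       root = po$edge[nrow(po$edge), 1])
}

# Conditional (down) partial likelihoods for one rate category.
# Returns list(partials = list of 4 x npat, scalers = list of per-pattern
# log-scalers).
down_partials <- function(po, n, prep, model, rate) {
  nn <- n + po$Nnode
  partial <- vector("list", nn)
  scaler <- vector("list", nn)
  for (i in seq_len(n)) {
    partial[[i]] <- prep$tips[[po$tip.label[i]]]
    scaler[[i]] <- numeric(prep$n_patterns)
  }
  edgeA <- vector("list", nrow(po$edge))  # P(t) %*% D[child], per edge
  for (e in seq_len(nrow(po$edge))) {
    p <- po$edge[e, 1]; ch <- po$edge[e, 2]
    P <- transition_probability(model, po$edge.length[e] * rate)
    A <- P %*% partial[[ch]]
    edgeA[[e]] <- A
    if (is.null(partial[[p]])) {
      partial[[p]] <- A
      scaler[[p]] <- scaler[[ch]]
    } else {
      partial[[p]] <- partial[[p]] * A
      scaler[[p]] <- scaler[[p]] + scaler[[ch]]
    }
    mx <- col_max(partial[[p]])
    if (any(mx < 1e-280)) {
      mx[mx == 0] <- 1
      partial[[p]] <- sweep(partial[[p]], 2, mx, "/")
      scaler[[p]] <- scaler[[p]] + log(mx)
    }
  }
  list(partials = partial, scalers = scaler, edgeA = edgeA)
}

#' Log-likelihood of an alignment on a tree (Felsenstein pruning)
#'
#' Standard pruning over compressed site patterns with per-node scaling to
#' prevent underflow; gaps, N and ? are fully ambiguous states. With a
#' +Gamma model the site likelihood is the average over the discrete
#' category likelihoods.
#'
#' @param tree a `phylo` tree whose tips match the alignment taxa; branch
#'   lengths in expected substitutions per site
#' @param aln character matrix (taxa x sites), or a prepared pattern object
#'   from the internal compressor
#' @param model a [substitution_model()]
#' @return the log-likelihood (natural log)
#' @export
log_likelihood <- function(tree, aln, model) {
  prep <- if (is.list(aln) && !is.null(aln$tips)) aln else
    compress_patterns(aln)
  sc <- tree_postorder(tree, prep$taxa)
  po <- sc$po; n <- sc$n; root <- sc$root
  rates <- model$category_rates
  percat <- matrix(0, length(rates), prep$n_patterns)
  scaled <- FALSE
  acc <- 0
  for (ci in seq_along(rates)) {
    dp <- down_partials(po, n, prep, model, rates[ci])
    lik <- as.vector(model$pi %*% dp$partials[[root]])
    if (any(dp$scalers[[root]] != 0)) scaled <- TRUE
    percat[ci, ] <- log(lik) + dp$scalers[[root]]
    acc <- acc + lik
  }
  sitelog <- if (length(rates) == 1) percat[1, ]
    else if (!scaled) log(acc / length(rates))
    else log_sum_exp(percat) - log(length(rates))
  sum(prep$weights * sitelog)
}

# -- branch-length optimization ----------------------------------------------

# "Outside" partials W[v] for every edge (p -> v): the likelihood of all
# data outside v's subtree, folded with the root prior, expressed at p's
# state, per category. lnL as a function of the length of edge (p -> v) is
# then sum over patterns of log mean_cat sum_a W[v]_a (P(t) D[v])_a.
edge_partials <- function(po, n, prep, model) {
  nrates <- length(model$category_rates)
  down <- lapply(model$category_rates, function(r)
    down_partials(po, n, prep, model, r))
  ne <- nrow(po$edge)
  nn <- n + po$Nnode
  root <- po$edge[ne, 1]
  # preorder = reverse postorder over edges
  W <- vector("list", nrates)
  sW <- vector("list", nrates)
  for (ci in seq_len(nrates)) {
    W[[ci]] <- vector("list", nn)
    sW[[ci]] <- vector("list", nn)
  }
  kids_edges <- split(seq_len(ne), po$edge[, 1])
  O <- lapply(seq_len(nrates), function(ci) {
    o <- vector("list", nn)
    o[[root]] <- matrix(model$pi, 4, prep$n_patterns)
    o
  })
  sO <- lapply(seq_len(nrates), function(ci) {
    s <- vector("list", nn)
    s[[root]] <- numeric(prep$n_patterns)
    s
  })
  for (e in rev(seq_len(ne))) {
    p <- po$edge[e, 1]; v <- po$edge[e, 2]
    sib <- setdiff(kids_edges[[as.character(p)]], e)
    for (ci in seq_len(nrates)) {
      dp <- down[[ci]]
      w <- O[[ci]][[p]]
      sw <- sO[[ci]][[p]]
      for (se in sib) {
        w <- w * dp$edgeA[[se]]
        sw <- sw + dp$scalers[[po$edge[se, 2]]]
      }
      mx <- col_max(w)
      if (any(mx < 1e-280)) {
        mx[mx == 0] <- 1
        w <- sweep(w, 2, mx, "/")
        sw <- sw + log(mx)
      }
      W[[ci]][[v]] <- w
      sW[[ci]][[v]] <- sw
      if (v > n) {
        P <- transition_probability(model,
                                    po$edge.length[e] *
                                      model$category_rates[ci])
        O[[ci]][[v]] <- crossprod(P, w)
        sO[[ci]][[v]] <- sw
      }
    }
  }
  list(down = down, W = W, sW = sW)
}

# Precompute, for one edge, the per-category spectral cross-products G_c =
# (U' W) * (V D) and scaler offsets, so the edge log-likelihood at any t is
# sum_pat w * log mean_c exp(offset_c) sum_m exp(lambda_m r_c t) G_c[m, ].
edge_profile <- function(ep, po, n, prep, model, e) {
  v <- po$edge[e, 2]
  nrates <- length(model$category_rates)
  G <- vector("list", nrates)
  off <- vector("list", nrates)
  for (ci in seq_len(nrates)) {
    dv <- ep$down[[ci]]$partials[[v]]
    G[[ci]] <- t((crossprod(model$U, ep$W[[ci]][[v]])) * (model$V %*% dv))
    off[[ci]] <- ep$sW[[ci]][[v]] + ep$down[[ci]]$scalers[[v]]
  }
  scaled <- any(vapply(off, function(o) any(o != 0), logical(1)))
  list(G = G, off = off, scaled = scaled,
       Gall = if (!scaled) do.call(cbind, G) else NULL)
}

edge_loglik_profile <- function(pr, prep, model, t) {
  nrates <- length(model$category_rates)
  if (nrates == 1) {
    lik <- pr$G[[1]] %*% exp(model$eigenvalues * t)
    return(sum(prep$weights * (log(lik + 1e-300) + pr$off[[1]])))
  }
  if (!pr$scaled) {
    e_all <- exp(model$eigenvalues * rep(t * model$category_rates, each = 4))
    acc <- pr$Gall %*% e_all
    return(sum(prep$weights * log(acc / nrates + 1e-300)))
  }
  percat <- matrix(0, nrates, prep$n_patterns)
  for (ci in seq_len(nrates)) {
    lik <- pr$G[[ci]] %*% exp(model$eigenvalues * (t * model$category_rates[ci]))
    percat[ci, ] <- log(pmax(as.vector(lik), 1e-300)) + pr$off[[ci]]
  }
  sum(prep$weights * (log_sum_exp(percat) - log(nrates)))
}

edge_loglik <- function(ep, po, n, prep, model, e, t) {
  pr <- edge_profile(ep, po, n, prep, model, e)
  edge_loglik_profile(pr, prep, model, t)
}

#' Optimize branch lengths of a tree under a substitution model
#'
#' Coordinate-wise Brent optimization of each branch length on
#' `[1e-8, 10]` using cached inside/outside partial likelihoods, swept until
#' the log-likelihood gain of a full sweep falls below `tol`. Each sweep's
#' proposal is accepted only if the full-tree log-likelihood improves
#' (with step-halving toward the previous lengths otherwise), so the
#' reported log-likelihood is non-decreasing.
#'
#' @param tree a `phylo` tree
#' @param aln alignment matrix or prepared patterns
#' @param model a [substitution_model()]
#' @param tol stop when a sweep gains less than this log-likelihood
#' @param max_sweeps sweep cap
#' @return list with `tree` (updated lengths), `logLik`
#' @export
optimize_branch_lengths <- function(tree, aln, model, tol = 1e-4,
                                    max_sweeps = 20) {
  prep <- if (is.list(aln) && !is.null(aln$tips)) aln else
    compress_patterns(aln)
  sc <- tree_postorder(tree, prep$taxa)
  po <- sc$po; n <- sc$n
  po$edge.length[po$edge.length < 1e-8] <- 1e-8
  cur <- log_likelihood(po, prep, model)
  for (sweep_i in seq_len(max_sweeps)) {
    ep <- edge_partials(po, n, prep, model)
    old_len <- po$edge.length
    new_len <- old_len
    for (e in seq_len(nrow(po$edge))) {
      pr <- edge_profile(ep, po, n, prep, model, e)
      opt <- stats::optimize(function(lt)
        -edge_loglik_profile(pr, prep, model, exp(lt)),
        interval = log(c(1e-8, 10)), tol = 1e-3)
      new_len[e] <- exp(opt$minimum)
    }
    step <- 1
    repeat {
      po$edge.length <- exp(step * log(new_len) + (1 - step) * log(old_len))
      val <- log_likelihood(po, prep, model)
      if (val >= cur - 1e-12 || step < 1 / 32) break
      step <- step / 2
    }
    if (val < cur) { po$edge.length <- old_len; break }
    gain <- val - cur
    cur <- val
    if (gain < tol) break
  }
  list(tree = po, logLik = cur)
}

# Alternate branch-length sweeps with 1-D searches over kappa and alpha.
optimize_model_params <- function(tree, prep, model, rounds = 2, tol = 1e-3) {
  fit <- optimize_branch_lengths(tree, prep, model, tol = tol)
  tree <- fit$tree; cur <- fit$logLik
  if (!(model$family %in% c("K80", "HKY85")) && !model$gamma)
    return(list(tree = tree, model = model, logLik = cur))
  for (r in seq_len(rounds)) {
    if (model$family %in% c("K80", "HKY85")) {
      opt <- stats::optimize(function(lk) {
        m <- substitution_model(model$family, kappa = exp(lk),
                                base_freq = model$pi, gamma = model$gamma,
                                alpha = model$alpha,
                                n_categories = max(4, model$n_categories))
        -log_likelihood(tree, prep, m)
      }, interval = log(c(0.05, 100)), tol = 1e-3)
      model <- substitution_model(model$family, kappa = exp(opt$minimum),
                                  base_freq = model$pi, gamma = model$gamma,
                                  alpha = model$alpha,
                                  n_categories = max(4, model$n_categories))
    }
    if (model$gamma) {
      opt <- stats::optimize(function(la) {
        m <- substitution_model(model$family, kappa = model$kappa,
                                base_freq = model$pi, gamma = TRUE,
                                alpha = exp(la),
                                n_categories = max(4, model$n_categories))
        -log_likelihood(tree, prep, m)
      }, interval = log(c(0.02, 50)), tol = 1e-3)
      model <- substitution_model(model$family, kappa = model$kappa,
                                  base_freq = model$pi, gamma = TRUE,
                                  alpha = exp(opt$minimum),
                                  n_categories = max(4, model$n_categories))
    }
    fit <- optimize_branch_lengths(tree, prep, model, tol = tol)
    tree <- fit$tree
    gain <- fit$logLik - cur
    cur <- fit$logLik
    if (gain < 0.1) break
  }
  list(tree = tree, model = model, logLik = cur)
}

count_parameters <- function(tree, model) {
  p <- nrow(tree$edge)
  if (model$family %in% c("K80", "HKY85")) p <- p + 1   # kappa
  if (model$family == "HKY85") p <- p + 3               # empirical pi
  if (model$gamma) p <- p + 1                           # alpha
  p
}

# JC69-corrected pairwise distances (ambiguous sites dropped pairwise).
jc_distance_matrix <- function(aln) {
  aln <- check_alignment(aln)
  nt <- nrow(aln)
  d <- matrix(0, nt, nt, dimnames = list(rownames(aln), rownames(aln)))
  for (i in seq_len(nt - 1)) for (j in (i + 1):nt) {
    ok <- aln[i, ] %in% c("A", "C", "G", "T") &
      aln[j, ] %in% c("A", "C", "G", "T")
    p <- if (any(ok)) mean(aln[i, ok] != aln[j, ok]) else 0
    p <- min(p, 0.74)
    d[i, j] <- d[j, i] <- -0.75 * log(1 - 4 * p / 3)
  }
  d
}

# Pairwise maximum-likelihood distance under an arbitrary model.
model_distance_matrix <- function(aln, model) {
  aln <- check_alignment(aln)
  nt <- nrow(aln)
  d <- matrix(0, nt, nt, dimnames = list(rownames(aln), rownames(aln)))
  for (i in seq_len(nt - 1)) for (j in (i + 1):nt) {
    ok <- aln[i, ] %in% c("A", "C", "G", "T") &
      aln[j, ] %in% c("A", "C", "G", "T")
    if (!any(ok)) { d[i, j] <- d[j, i] <- 0; next }
    ia <- match(aln[i, ok], c("A", "C", "G", "T"))
    ib <- match(aln[j, ok], c("A", "C", "G", "T"))
    tab <- matrix(0, 4, 4)
    for (s in seq_along(ia)) tab[ia[s], ib[s]] <- tab[ia[s], ib[s]] + 1
    nll <- function(lt) {
      t <- exp(lt)
      # average P over categories, then sum tab * log(pi_a P_ab)
      Pbar <- Reduce(`+`, lapply(model$category_rates, function(r)
        transition_probability(model, t * r))) / length(model$category_rates)
      -sum(tab * log(pmax(model$pi * Pbar, 1e-300)))
    }
    opt <- stats::optimize(nll, interval = log(c(1e-6, 5)), tol = 1e-5)
    d[i, j] <- d[j, i] <- exp(opt$minimum)
  }
  d
}

#' AIC model selection over a fixed candidate set
#'
#' Fits each candidate model on the same NJ topology (branch lengths
#' re-optimized per candidate; kappa and Gamma shape by bounded 1-D search;
#' base frequencies empirical for HKY85) and ranks them by
#' AIC = 2 * parameters - 2 * lnL. The candidate set {JC69, K80, HKY85}
#' x {+G, without} is a deliberate compact subset of the usual model-test
#' batteries: enough to distinguish frequency, ts/tv and rate-variation
#' structure.
#'
#' @param aln character alignment matrix, >= 3 taxa
#' @param candidates character vector of candidate names among
#'   `"JC69", "JC69+G", "K80", "K80+G", "HKY85", "HKY85+G"`
#' @return object of class `model_test`: a data frame (`model`, `logLik`,
#'   `n_params`, `AIC`, `delta_AIC`) sorted by AIC, with attribute `fits`
#'   (per-model tree + model) and `best`
#' @export
model_test <- function(aln, candidates = c("JC69", "JC69+G", "K80", "K80+G",
                                           "HKY85", "HKY85+G")) {
  aln <- check_alignment(aln)
  if (nrow(aln) < 3) stop("model test needs >= 3 taxa")
  prep <- compress_patterns(aln)
  freq <- empirical_base_freq(aln)
  topo <- neighbor_joining(jc_distance_matrix(aln))
  rows <- list(); fits <- list()
  warm <- list()   # optimized trees per family, reused as +G warm starts
  for (cand in candidates) {
    fam <- sub("\\+G$", "", cand)
    g <- grepl("\\+G$", cand)
    model <- substitution_model(fam, kappa = 2,
                                base_freq = if (fam == "HKY85") freq else NULL,
                                gamma = g, alpha = 0.5)
    start <- if (!is.null(warm[[fam]])) warm[[fam]] else topo
    fit <- tryCatch(optimize_model_params(start, prep, model, tol = 1e-2),
                    error = function(e) NULL)
    if (is.null(fit)) {
      warning("optimization failed for candidate ", cand)
      next
    }
    p <- count_parameters(fit$tree, fit$model)
    rows[[cand]] <- data.frame(model = cand, logLik = fit$logLik,
                               n_params = p, AIC = 2 * p - 2 * fit$logLik)
    fits[[cand]] <- fit
    if (!g) warm[[fam]] <- fit$tree
  }
  tab <- do.call(rbind, rows)
  tab <- tab[order(tab$AIC), ]
  tab$delta_AIC <- tab$AIC - tab$AIC[1]
  rownames(tab) <- NULL
  structure(tab, class = c("model_test", "data.frame"),
            fits = fits, best = tab$model[1])
}

#' @export
print.model_test <- function(x, ...) {
  cat("Substitution model selection by AIC (best first):\n")
  print.data.frame(cbind(x["model"], round(x[c("logLik", "AIC",
                                               "delta_AIC")], 2),
                         x["n_params"]), row.names = FALSE)
  invisible(x)
}

# All NNI rearrangements of an unrooted tree (two per internal edge).
nni_neighbors <- function(phy) {
  n <- length(phy$tip.label)
  out <- list()
  for (e in seq_len(nrow(phy$edge))) {
    ch <- phy$edge[e, 2]
    if (ch <= n) next
    p <- phy$edge[e, 1]
    kids_c <- which(phy$edge[, 1] == ch)
    sib <- setdiff(which(phy$edge[, 1] == p), e)
    if (!length(sib) || length(kids_c) < 2) next
    z <- sib[1]
    for (xe in kids_c[1:2]) {
      e2 <- phy$edge
      e2[xe, 1] <- p
      e2[z, 1] <- ch
      cand <- phy
      cand$edge <- e2
      cand <- tryCatch(ape::reorder.phylo(cand, "cladewise"),
                       error = function(err) NULL)
      if (!is.null(cand)) out[[length(out) + 1L]] <- cand
    }
  }
  out
}

#' Maximum-likelihood tree search (NJ start, NNI rearrangements)
#'
#' Starts from the neighbor-joining tree on pairwise maximum-likelihood
#' distances under `model`, optimizes branch lengths, and repeatedly applies
#' the best improving nearest-neighbor interchange (branch lengths
#' re-optimized per candidate) until no rearrangement improves the
#' log-likelihood. Deterministic given the input.
#'
#' @param aln character alignment matrix, >= 4 taxa
#' @param model a [substitution_model()]
#' @param optimize_params also refine kappa/alpha during the search
#' @return object of class `model_fit`: `tree`, `model`, `logLik`,
#'   `n_params`, `AIC`
#' @export
ml_search <- function(aln, model, optimize_params = FALSE) {
  aln <- check_alignment(aln)
  if (nrow(aln) < 4) stop("ML search needs >= 4 taxa")
  prep <- compress_patterns(aln)
  start <- neighbor_joining(model_distance_matrix(aln, model))
  fit <- if (optimize_params) optimize_model_params(start, prep, model)
         else c(optimize_branch_lengths(start, prep, model),
                list(model = model))
  start_logLik <- fit$logLik
  # rank rearrangements with a cheap two-sweep score; full optimization at
  # the end only
  quick <- function(tr) optimize_branch_lengths(tr, prep, fit$model,
                                                tol = 2e-2, max_sweeps = 2)
  cur <- quick(fit$tree)
  repeat {
    improved <- FALSE
    for (cand in nni_neighbors(cur$tree)) {
      cf <- quick(cand)
      if (cf$logLik > cur$logLik + 1e-6) {
        cur <- cf
        improved <- TRUE
      }
    }
    if (!improved) break
  }
  final <- optimize_branch_lengths(cur$tree, prep, fit$model)
  if (final$logLik >= start_logLik) {
    fit$tree <- final$tree
    fit$logLik <- final$logLik
  }
  p <- count_parameters(fit$tree, fit$model)
  structure(list(tree = fit$tree, model = fit$model, logLik = fit$logLik,
                 n_params = p, AIC = 2 * p - 2 * fit$logLik),
            class = "model_fit")
}

#' @export
print.model_fit <- function(x, ...) {
  cat("Maximum-likelihood fit: ", x$model$family,
      if (x$model$gamma) "+G", ", ", length(x$tree$tip.label), " taxa\n",
      sep = "")
  cat(sprintf("lnL = %.3f, %d parameters, AIC = %.3f\n", x$logLik,
              x$n_params, x$AIC))
  invisible(x)
}

#' @export
logLik.model_fit <- function(object, ...) {
  structure(object$logLik, df = object$n_params, class = "logLik")
}

#' Nonparametric bootstrap supports for the ML tree
#'
#' Resamples alignment columns with replacement, re-runs the NNI search from
#' the full-data ML topology per replicate (the standard reduced-effort
#' bootstrap), and maps bipartition percentages onto the full-data tree.
#'
#' @param aln character alignment matrix
#' @param model a [substitution_model()]
#' @param n_reps bootstrap replicates (default 1000)
#' @param seed optional integer seed
#' @param full_fit optionally a precomputed [ml_search()] result on `aln`
#' @return the ML `phylo` tree with `node.label` supports (percent)
#' @export
bootstrap_ml <- function(aln, model, n_reps = 1000, seed = NULL,
                         full_fit = NULL) {
  aln <- check_alignment(aln)
  if (is.null(full_fit)) full_fit <- ml_search(aln, model)
  full_tree <- full_fit$tree
  full_splits <- tree_bipartitions(full_tree)
  counts <- stats::setNames(numeric(length(full_splits)), full_splits)
  n_ok <- 0L; n_fail <- 0L
  with_seed(seed, {
    for (b in seq_len(n_reps)) {
      cols <- sample.int(ncol(aln), ncol(aln), replace = TRUE)
      rep_aln <- aln[, cols, drop = FALSE]
      rep_splits <- tryCatch({
        prep <- compress_patterns(rep_aln)
        fit <- optimize_branch_lengths(full_tree, prep, model,
                                       tol = 2e-2, max_sweeps = 2)
        best <- fit
        for (cand in nni_neighbors(fit$tree)) {
          cf <- optimize_branch_lengths(cand, prep, model,
                                        tol = 2e-2, max_sweeps = 2)
          if (cf$logLik > best$logLik + 1e-6) best <- cf
        }
        tree_bipartitions(best$tree)
      }, error = function(e) NULL)
      if (is.null(rep_splits)) { n_fail <- n_fail + 1L; next }
      n_ok <- n_ok + 1L
      hit <- names(counts) %in% rep_splits
      counts[hit] <- counts[hit] + 1
    }
  })
  if (n_fail > 0) warning(n_fail, " bootstrap replicate(s) failed")
  if (n_ok == 0) stop("all bootstrap replicates failed")
  n <- length(full_tree$tip.label)
  node_lab <- rep("", full_tree$Nnode)
  for (node_chr in names(full_splits)) {
    v <- as.integer(node_chr)
    node_lab[v - n] <- sprintf("%.0f",
                               100 * counts[[full_splits[[node_chr]]]] / n_ok)
  }
  full_tree$node.label <- node_lab
  attr(full_tree, "n_effective") <- n_ok
  attr(full_tree, "n_failed") <- n_fail
  full_tree
}
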