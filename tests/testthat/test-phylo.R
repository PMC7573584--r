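test_that("alignment trimming keeps the leading columns", {
  set.seed(1)
  aln <- matrix(sample(c("A", "C", "G", "T"), 3 * 658, TRUE), 3, 658,
                dimnames = list(paste0("t", 1:3), NULL))
  tr <- trim_alignment(aln, 550)
  expect_equal(dim(tr), c(3, 550))
  expect_identical(tr, aln[, 1:550])
  expect_identical(trim_alignment(tr, 550), tr)   # idempotent
  expect_error(trim_alignment(aln[, 1:500], 550), "short")
})

test_that("substitution models are reversible with unit mean rate", {
  for (m in list(substitution_model("JC69"),
                 substitution_model("K80", kappa = 5),
                 substitution_model("HKY85", kappa = 3,
                                    base_freq = c(.4, .1, .2, .3)))) {
    expect_equal(unname(rowSums(m$Q)), rep(0, 4), tolerance = 1e-12)
    expect_equal(-sum(m$pi * diag(m$Q)), 1, tolerance = 1e-12)
    # detailed balance pi_i q_ij = pi_j q_ji
    expect_equal(m$pi * m$Q, t(m$pi * m$Q), tolerance = 1e-12,
                 ignore_attr = TRUE)
    P <- transition_probability(m, 0.37)
    expect_equal(rowSums(P), rep(1, 4), tolerance = 1e-12)
    expect_equal(transition_probability(m, 0), diag(4), tolerance = 1e-9,
                 ignore_attr = TRUE)
  }
  # Gamma category rates average exactly 1 for any shape
  for (a in c(0.05, 0.4, 1, 7))
    expect_equal(mean(gamma_category_rates(a, 4)), 1, tolerance = 1e-9)
})

test_that("pruning matches closed forms on two sequences", {
  # identical sequences at distance 0: lnL = sum log pi(base)
  m <- substitution_model("HKY85", kappa = 2, base_freq = c(.3, .2, .2, .3))
  seqs <- c("A", "C", "G", "T", "A", "C")
  aln <- rbind(t1 = seqs, t2 = seqs)
  tree <- parse_newick("(t1:0,t2:0);")
  expect_equal(log_likelihood(tree, aln, m),
               sum(log(m$pi[seqs])), tolerance = 1e-10)
  # JC69 pairwise closed form at distance t
  t <- 0.23
  mj <- substitution_model("JC69")
  aln2 <- rbind(t1 = c("A", "A", "G", "T"), t2 = c("A", "C", "G", "T"))
  tree2 <- parse_newick(sprintf("(t1:%f,t2:0);", t))
  p_same <- log(0.25 * (0.25 + 0.75 * exp(-4 * t / 3)))
  p_diff <- log(0.25 * (0.25 - 0.25 * exp(-4 * t / 3)))
  expect_equal(log_likelihood(tree2, aln2, mj), 3 * p_same + p_diff,
               tolerance = 1e-10)
})

test_that("pruning equals exhaustive ancestral-state enumeration on 4 taxa", {
  m <- substitution_model("HKY85", kappa = 3, base_freq = c(.35, .15, .2, .3))
  aln <- rbind(t1 = c("A", "C", "G", "T"), t2 = c("A", "C", "T", "T"),
               t3 = c("G", "C", "G", "A"), t4 = c("A", "T", "G", "T"))
  bl <- list(t1 = 0.1, t2 = 0.2, t3 = 0.15, t4 = 0.3, internal = 0.12)
  tree <- parse_newick(sprintf("((t1:%f,t2:%f):%f,t3:%f,t4:%f);",
                               bl$t1, bl$t2, bl$internal, bl$t3, bl$t4))
  expect_equal(log_likelihood(tree, aln, m),
               oracle_4taxon_loglik(aln, m, bl), tolerance = 1e-10)
})

test_that("HKY with kappa 1 and equal frequencies reduces to JC69", {
  set.seed(2)
  tr <- ape::unroot(ape::rtree(6))
  tr$edge.length <- runif(nrow(tr$edge), 0.05, 0.5)
  aln <- simulate_sequences(tr, substitution_model("JC69"), 200, seed = 3)
  expect_equal(log_likelihood(tr, aln, substitution_model("HKY85", kappa = 1)),
               log_likelihood(tr, aln, substitution_model("JC69")),
               tolerance = 1e-10)
})

test_that("likelihood is invariant to re-rooting and ignores all-gap columns", {
  set.seed(4)
  tr <- ape::unroot(ape::rtree(6))
  tr$edge.length <- runif(nrow(tr$edge), 0.05, 0.5)
  m <- substitution_model("HKY85", kappa = 2, base_freq = c(.3, .2, .25, .25),
                          gamma = TRUE, alpha = 0.6)
  aln <- simulate_sequences(tr, m, 150, seed = 5)
  ll <- log_likelihood(tr, aln, m)
  for (node in c(1, 3)) {
    rr <- ape::unroot(ape::root(tr, node))
    expect_equal(log_likelihood(rr, aln, m), ll, tolerance = 1e-8)
  }
  gappy <- cbind(aln, matrix("-", nrow(aln), 7))
  expect_equal(log_likelihood(tr, gappy, m), ll, tolerance = 1e-8)
})

test_that("pruning agrees with the reference phylogenetics implementation", {
  skip_if_not_installed("phangorn")
  set.seed(6)
  tr <- ape::unroot(ape::rtree(7))
  tr$edge.length <- runif(nrow(tr$edge), 0.05, 0.4)
  m <- substitution_model("HKY85", kappa = 3, base_freq = c(.3, .2, .25, .25),
                          gamma = TRUE, alpha = 0.4)
  aln <- simulate_sequences(tr, m, 300, seed = 7)
  fit <- phangorn::pml(tr, phangorn::phyDat(aln), bf = m$pi,
                       Q = c(1, 3, 1, 1, 3, 1), k = 4, shape = 0.4)
  expect_equal(log_likelihood(tr, aln, m), fit$logLik, tolerance = 1e-6)
})

test_that("model selection reports a coherent AIC table", {
  set.seed(8)
  tr <- ape::unroot(ape::rtree(6))
  tr$edge.length <- runif(nrow(tr$edge), 0.05, 0.3)
  aln <- simulate_sequences(tr, substitution_model("JC69"), 250, seed = 9)
  mt <- model_test(aln)
  expect_equal(nrow(mt), 6)
  expect_equal(mt$AIC, 2 * mt$n_params - 2 * mt$logLik, tolerance = 1e-9)
  expect_equal(mt$AIC, sort(mt$AIC))
  expect_equal(mt$delta_AIC[1], 0)
  # branch count + kappa + alpha + empirical frequencies
  expect_equal(mt$n_params[mt$model == "HKY85+G"] -
                 mt$n_params[mt$model == "JC69"], 5)
})

test_that("ML search improves on its start and is deterministic", {
  set.seed(10)
  tr <- ape::unroot(ape::rtree(6))
  tr$edge.length <- runif(nrow(tr$edge), 0.05, 0.4)
  m <- substitution_model("K80", kappa = 4)
  aln <- simulate_sequences(tr, m, 300, seed = 11)
  start <- neighbor_joining(wingmorph:::model_distance_matrix(aln, m))
  fit <- ml_search(aln, m)
  expect_gte(fit$logLik, log_likelihood(start, aln, m))
  expect_equal(fit$AIC, 2 * fit$n_params - 2 * fit$logLik, tolerance = 1e-9)
  fit2 <- ml_search(aln, m)
  expect_identical(write_newick(fit$tree), write_newick(fit2$tree))
  expect_identical(fit$logLik, fit2$logLik)
})

test_that("ML bootstrap gives full support under strong signal and repeats under a seed", {
  m <- substitution_model("HKY85", kappa = 3, base_freq = c(.3, .2, .2, .3))
  tr <- parse_newick("((A:0.15,B:0.15):0.12,(C:0.15,D:0.15):0.12,E:0.2);")
  aln <- simulate_sequences(tr, m, 550, seed = 12)
  b1 <- bootstrap_ml(aln, m, n_reps = 15, seed = 13)
  b2 <- bootstrap_ml(aln, m, n_reps = 15, seed = 13)
  expect_identical(b1$node.label, b2$node.label)
  sup <- as.numeric(b1$node.label[nzchar(b1$node.label)])
  expect_true(all(sup >= 70))
})

test_that("sequence simulation matches its generating model", {
  m <- substitution_model("HKY85", kappa = 2, base_freq = c(.4, .1, .2, .3))
  tr0 <- parse_newick("(a:0,b:0,c:0.4);")
  aln0 <- simulate_sequences(tr0, m, 400, seed = 14)
  expect_identical(aln0["a", ], aln0["b", ])     # zero branch, same sequence
  # base composition converges to pi
  big <- simulate_sequences(parse_newick("(a:0.1,b:0.1,c:0.1);"), m,
                            50000, seed = 15)
  emp <- table(factor(big, c("A", "C", "G", "T"))) / length(big)
  expect_equal(as.vector(emp), as.vector(m$pi), tolerance = 0.01)
  expect_identical(simulate_sequences(tr0, m, 50, seed = 16),
                   simulate_sequences(tr0, m, 50, seed = 16))
})

test_that("FASTA round-trips through the alignment reader", {
  aln <- rbind(s1 = c("A", "C", "G", "T", "-"),
               s2 = c("A", "C", "G", "A", "N"))
  f <- withr::local_tempfile(fileext = ".fasta")
  write_fasta_alignment(aln, f)
  back <- read_fasta_alignment(f)
  expect_identical(unname(back), unname(aln))
  expect_identical(rownames(back), rownames(aln))
})
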