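test_that("the seven packaged models are valid reversible rate matrices", {
  for (m in c("JTT", "LG", "WAG", "Blosum62", "MtREV", "VT", "Dayhoff")) {
    sm <- subst_model(m)
    expect_equal(sum(sm$freqs), 1, tolerance = 1e-12)
    expect_true(all(sm$freqs > 0))
    expect_equal(max(abs(rowSums(sm$Q))), 0, tolerance = 1e-10)
    expect_equal(-sum(sm$freqs * diag(sm$Q)), 1, tolerance = 1e-10)
    # detailed balance: pi_i q_ij == pi_j q_ji
    F <- sm$freqs * sm$Q
    expect_equal(max(abs(F - t(F))), 0, tolerance = 1e-10)
    # transition probabilities are stochastic and converge to equilibrium
    P <- selevo:::model_prob_matrix(sm, 500)
    expect_lt(max(abs(sweep(P, 2, sm$freqs))), 1e-4)
  }
  expect_error(subst_model("GTR"), "arg")
})

test_that("BioNJ handles the 2- and 3-taxon closed forms", {
  d2 <- matrix(c(0, 0.8, 0.8, 0), 2, dimnames = list(c("a", "b"), c("a", "b")))
  t2 <- bionj_tree(d2)
  expect_equal(sort(t2$edge.length), c(0.4, 0.4))
  # three taxa: branch lengths from the three-point formulas
  d3 <- matrix(0, 3, 3, dimnames = list(c("a", "b", "c"), c("a", "b", "c")))
  d3["a", "b"] <- d3["b", "a"] <- 0.5
  d3["a", "c"] <- d3["c", "a"] <- 0.7
  d3["b", "c"] <- d3["c", "b"] <- 0.8
  t3 <- bionj_tree(d3)
  len <- setNames(t3$edge.length, t3$tip.label[t3$edge[, 2]])
  expect_equal(unname(len["a"]), (0.5 + 0.7 - 0.8) / 2, tolerance = 1e-6)
  expect_equal(unname(len["b"]), (0.5 + 0.8 - 0.7) / 2, tolerance = 1e-6)
  expect_equal(unname(len["c"]), (0.7 + 0.8 - 0.5) / 2, tolerance = 1e-6)
  expect_error(bionj_tree(matrix(c(0, 1, 2, 0), 2)), "symmetric")
})

test_that("BioNJ reconstructs additive matrices exactly", {
  set.seed(601)
  for (n in c(5, 8)) {
    tr <- ape::rtree(n)
    d <- ape::cophenetic.phylo(tr)
    bt <- bionj_tree(d)
    expect_equal(ape::dist.topo(ape::unroot(tr), bt), 0, ignore_attr = TRUE)
    expect_equal(max(abs(ape::cophenetic.phylo(bt)[rownames(d), colnames(d)] - d)),
                 0, tolerance = 1e-5)
  }
})

test_that("pruning equals brute-force summation over ancestral states", {
  set.seed(602)
  for (m in c("JTT", "MtREV", "Blosum62")) {
    sm <- subst_model(m)
    tr <- random_named_tree(4)
    aln <- evolve_aa_alignment(tr, sm, 3, seed = 11)
    mine <- fixed_topology_loglik(aln, tr, sm, optimize = FALSE)$logL
    expect_equal(mine, oracle_tree_loglik(aln, tr, sm), tolerance = 1e-9)
  }
})

test_that("log-likelihood is invariant under rerooting and taxon order", {
  set.seed(603)
  tr <- random_named_tree(5)
  aln <- evolve_aa_alignment(tr, "JTT", 60, seed = 12)
  base <- fixed_topology_loglik(aln, tr, "JTT", optimize = FALSE)$logL
  rr <- ape::root(ape::unroot(tr), outgroup = "t3", resolve.root = TRUE)
  expect_equal(fixed_topology_loglik(aln, rr, "JTT", optimize = FALSE)$logL,
               base, tolerance = 1e-7)
  expect_equal(fixed_topology_loglik(aln[sample(rownames(aln)), ], tr, "JTT",
                                     optimize = FALSE)$logL,
               base, tolerance = 1e-9)
})

test_that("two identical tips at vanishing distance approach log(pi)", {
  tr <- ape::read.tree(text = "(a:1e-9,b:1e-9);")
  sm <- subst_model("WAG")
  ll <- fixed_topology_loglik(c(a = "M", b = "M"), tr, sm,
                              optimize = FALSE)$logL
  expect_equal(ll, log(sm$freqs[["M"]]), tolerance = 1e-6)
})

test_that("branch optimization is monotone and never returns negative lengths", {
  set.seed(604)
  tr <- random_named_tree(5)
  aln <- evolve_aa_alignment(tr, "LG", 80, seed = 13)
  start <- fixed_topology_loglik(aln, tr, "LG", optimize = FALSE)
  fit <- fixed_topology_loglik(aln, tr, "LG")
  expect_gte(fit$logL, start$logL)
  expect_true(all(fit$tree$edge.length >= 0))
})

test_that("AIC ranking is 2k - 2logL with the best models flagged", {
  set.seed(605)
  tr <- random_named_tree(4)
  aln <- evolve_aa_alignment(tr, "JTT", 120, seed = 14)
  tab <- aic_rank(aln, tr, models = c("JTT", "WAG", "Dayhoff"))
  expect_equal(tab$AIC, 2 * tab$k - 2 * tab$logL)
  expect_equal(tab$AIC, sort(tab$AIC))
  expect_equal(sum(tab$top2), 2)
  # equal-k models differing by 5 logL units are 10 AIC units apart
  expect_equal(diff(tab$AIC), -2 * diff(tab$logL))
  # a duplicated model ties
  tab2 <- aic_rank(aln, tr, models = c("WAG", "WAG"))
  expect_equal(tab2$rank, c(1L, 1L))
})

test_that("NNI search is a fixed point at the truth and recovers it otherwise", {
  set.seed(606)
  true_tree <- ape::read.tree(text = "((a:0.15,b:0.15):0.3,(c:0.15,d:0.15):0.3);")
  aln <- evolve_aa_alignment(true_tree, "JTT", 400, seed = 15)
  fit_true <- nni_search(aln, true_tree, "JTT")
  expect_equal(ape::dist.topo(ape::unroot(fit_true$tree),
                              ape::unroot(true_tree)), 0, ignore_attr = TRUE)
  # start from the wrong resolution
  wrong <- ape::read.tree(text = "((a:0.2,c:0.2):0.2,(b:0.2,d:0.2):0.2);")
  fit <- nni_search(aln, wrong, "JTT")
  expect_equal(ape::dist.topo(ape::unroot(fit$tree),
                              ape::unroot(true_tree)), 0, ignore_attr = TRUE)
  start_ll <- fixed_topology_loglik(aln, wrong, "JTT")$logL
  expect_gte(fit$logL, start_ll)
})

test_that("aLRT support follows the chi-square mixture", {
  set.seed(607)
  tr <- ape::read.tree(text = "((a:0.1,b:0.1)ab:0.4,(c:0.1,d:0.1)cd:0.4);")
  tr <- selevo:::validate_species_tree(tr)
  aln <- evolve_aa_alignment(tr, "WAG", 300, seed = 16)
  res <- alrt_support(aln, tr, "WAG", "ab")
  expect_true(res$support >= 0 && res$support <= 1)
  expect_equal(res$support, 0.5 + 0.5 * pchisq(res$statistic, 1))
  # well-supported branch on abundant data
  expect_gte(res$support, 0.95)
  # terminal branches are not applicable
  expect_error(alrt_support(aln, tr, "WAG", "a"), "internal")
  # uninformative data floors at the mixture CDF at zero
  flat <- matrix("A", 4, 10, dimnames = list(c("a", "b", "c", "d"), NULL))
  res0 <- alrt_support(flat, tr, "WAG", "ab")
  expect_equal(res0$statistic, 0, tolerance = 1e-6)
  expect_equal(res0$support, 0.5, tolerance = 1e-3)
})

test_that("the full workflow ranks the generating model first on clean data", {
  set.seed(608)
  tr <- random_named_tree(6)
  tr$edge.length <- runif(nrow(tr$edge), 0.1, 0.5)
  aln <- evolve_aa_alignment(tr, "JTT", 400, seed = 17)
  res <- bestml(aln, models = c("JTT", "WAG", "MtREV"), support = FALSE)
  expect_equal(res$aic$model[1], "JTT")
  expect_s3_class(res$best$tree, "phylo")
})
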