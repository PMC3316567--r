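test_that("genome simulation is a pure function of its seed", {
  cfg <- sim_config(seed = 9, n_genes = 2, genome_length = 6000)
  s1 <- simulate_genome(cfg)
  s2 <- simulate_genome(cfg)
  expect_identical(s1$sequence, s2$sequence)
  expect_identical(s1$truth, s2$truth)
  s3 <- simulate_genome(sim_config(seed = 10, n_genes = 2, genome_length = 6000))
  expect_false(identical(s1$sequence, s3$sequence))
})

test_that("zero genes give an empty truth set and a full-length sequence", {
  sim <- simulate_genome(sim_config(seed = 1, n_genes = 0,
                                    genome_length = 2000))
  expect_equal(nrow(sim$truth), 0)
  expect_equal(nchar(sim$sequence), 2000)
})

test_that("features that cannot fit raise a capacity error", {
  expect_error(simulate_genome(sim_config(seed = 1, n_genes = 5,
                                          genome_length = 1500)),
               "capacity")
})

test_that("planted gene models carry an in-frame UGA and a valid SECIS", {
  sim <- simulate_genome(sim_config(seed = 21, n_genes = 3))
  for (i in seq_len(nrow(sim$truth))) {
    t1 <- sim$truth[i, ]
    expect_equal(substr(sim$sequence, t1$sec_start + 1, t1$sec_end), "TGA")
    cds <- substr(sim$sequence, t1$cds_start + 1, t1$cds_end)
    expect_equal(nchar(cds) %% 3, 0)
    expect_equal(substr(cds, 1, 3), "ATG")
    # the planted SECIS passes the scanner's own grammar on its locus
    local <- substr(sim$sequence, t1$secis_start + 1, t1$secis_end)
    h <- scan_secis(local, both_strands = FALSE)
    expect_gte(nrow(h), 1)
  }
})

test_that("codon evolution respects time zero and the omega limits", {
  a <- random_cds(150)
  expect_identical(evolve_codons(a, omega = 1, t = 0, seed = 3), a)
  # omega = 0: all fixed differences are synonymous
  b <- evolve_codons(a, omega = 0, t = 2, seed = 4)
  ca <- selevo:::split_codons(a); cb <- selevo:::split_codons(b)
  gc <- selevo:::genetic_code()
  expect_true(all(gc[ca] == gc[cb]))
  expect_false(identical(a, b))
  # no stop codons are ever introduced
  expect_false(any(gc[cb] == "*"))
  # determinism
  expect_identical(evolve_codons(a, 0.5, 0.3, seed = 8),
                   evolve_codons(a, 0.5, 0.3, seed = 8))
  expect_error(evolve_codons(paste0(a, "TAA"), 1, 0.1), "stop")
})

test_that("pseudogenization operators have the documented local effects", {
  cds <- paste0("ATG", "TGG", "AAA", "CCC", "GGG", "TAA")
  # premature stop on a TGG codon is the single-base TGG -> TAG change
  ps <- pseudogenize(cds, list(list(type = "premature_stop", pos = 2)))
  expect_equal(as.vector(substr(ps, 4, 6)), "TAG")
  expect_equal(nchar(ps), nchar(cds))
  # triplet deletion shortens by 3 and preserves downstream frame
  td <- pseudogenize(cds, list(list(type = "triplet_deletion", pos = 3)))
  expect_equal(nchar(td), nchar(cds) - 3)
  expect_equal(as.vector(substring(td, 7)), "CCCGGGTAA")
  # frameshift rejects multiples of three
  expect_error(pseudogenize(cds, list(list(type = "frameshift_indel",
                                           pos = 4, len = 3))),
               "multiple of 3")
  fs <- pseudogenize(cds, list(list(type = "frameshift_indel", pos = 4,
                                    len = -1)))
  expect_equal(nchar(fs), nchar(cds) - 1)
  # empty lesion list is the identity
  expect_equal(as.character(pseudogenize(cds, list())), cds)
  # SECIS core mutation turns GA into GG
  el <- generate_secis()
  core_pos <- el$core3_start + 1L
  mut <- pseudogenize(el$seq, list(list(type = "secis_core_mutation",
                                        pos = core_pos)))
  expect_equal(as.vector(substr(mut, core_pos, core_pos + 1)), "GG")
  # out-of-range lesions are range errors
  expect_error(pseudogenize(cds, list(list(type = "premature_stop", pos = 99))),
               "outside")
})

test_that("amino-acid alignment evolution matches the tree and seed", {
  tr <- random_named_tree(5, seed = 61)
  a1 <- evolve_aa_alignment(tr, "JTT", 40, seed = 5)
  a2 <- evolve_aa_alignment(tr, "JTT", 40, seed = 5)
  expect_identical(a1, a2)
  expect_equal(dim(a1), c(5, 40))
  expect_setequal(rownames(a1), tr$tip.label)
  # zero sites: empty alignment with the right taxon set
  a0 <- evolve_aa_alignment(tr, "WAG", 0, seed = 5)
  expect_equal(dim(a0), c(5, 0))
  # zero-length branches copy the root state to every tip
  tr0 <- tr; tr0$edge.length[] <- 0
  a3 <- evolve_aa_alignment(tr0, "LG", 25, seed = 6)
  expect_true(all(apply(a3, 2, function(col) length(unique(col)) == 1)))
  expect_error(evolve_aa_alignment(tr, "GTR20", 10), "arg")
})
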