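test_that("UTR lengths are spliced-transcript counts around the CDS", {
  # single-exon gene: 10 nt before ATG, 20 nt after the stop codon
  g <- coding_gene("g1", "chr", "+", exons = rbind(c(0L, 120L)),
                   cds = c(10L, 100L))
  expect_equal(utr_lengths(g), c(utr5_len = 10, utr3_len = 20))
  # CDS flush with the transcript ends
  g2 <- coding_gene("g2", "chr", "+", exons = rbind(c(0L, 90L)),
                    cds = c(0L, 90L))
  expect_equal(utr_lengths(g2), c(utr5_len = 0, utr3_len = 0))
  # 3'-UTR split across two exons (30 + 70 nt)
  g3 <- coding_gene("g3", "chr", "+",
                    exons = rbind(c(0L, 130L), c(200L, 270L)),
                    cds = c(10L, 100L))
  expect_equal(unname(utr_lengths(g3)["utr3_len"]), 100)
})

test_that("UGA-to-SECIS distances are exclusive spliced counts with a floor flag", {
  g <- toy_gene()
  # Sec codon 30: UGA occupies transcript [97,100); core at t=346
  d <- uga_to_secis_distance(g)
  expect_equal(d$distance, 246)
  expect_false(d$below_min)
  # engineered spacing: UGA ends at spliced position 150 (1-based), the core
  # starts at position 457, so 306 bases lie strictly between them
  g2 <- coding_gene("g4", "chr", "+", exons = rbind(c(0L, 600L)),
                    cds = c(0L, 300L), sec_codons = 50L,
                    secis = rbind(c(450L, 520L)), secis_core = 456L)
  expect_equal(uga_to_secis_distance(g2)$distance, 306)
  # adjacency gives zero; short spacing is returned but flagged
  g3 <- coding_gene("g5", "chr", "+", exons = rbind(c(0L, 400L)),
                    cds = c(0L, 150L), sec_codons = 10L,
                    secis = rbind(c(30L, 100L)), secis_core = 30L)
  expect_equal(uga_to_secis_distance(g3)$distance, 0)
  expect_true(uga_to_secis_distance(g3)$below_min)
  g3$secis_core <- 110L
  d3 <- uga_to_secis_distance(g3)
  expect_equal(d3$distance, 80)
  expect_true(d3$below_min)
  # SECIS strictly upstream of the UGA is an orientation error
  g4 <- coding_gene("g6", "chr", "+", exons = rbind(c(0L, 400L)),
                    cds = c(100L, 400L), sec_codons = 50L,
                    secis = rbind(c(0L, 60L)), secis_core = 0L)
  expect_error(uga_to_secis_distance(g4), "orientation")
})

test_that("an intron between UGA and SECIS leaves the distance unchanged", {
  g <- coding_gene("g1", "chr", "+", exons = rbind(c(0L, 500L)),
                   cds = c(0L, 300L), sec_codons = 20L,
                   secis = rbind(c(400L, 460L)), secis_core = 405L)
  # same transcript with a 200 nt intron inserted at genomic position 350
  g2 <- coding_gene("g1i", "chr", "+",
                    exons = rbind(c(0L, 350L), c(550L, 700L)),
                    cds = c(0L, 300L), sec_codons = 20L,
                    secis = rbind(c(600L, 660L)), secis_core = 605L)
  expect_equal(uga_to_secis_distance(g2)$distance,
               uga_to_secis_distance(g)$distance)
  expect_equal(stop_to_secis_distance(g2), stop_to_secis_distance(g))
})

test_that("a gene and its reverse-complement mirror yield identical features", {
  set.seed(301)
  sim <- simulate_genome(sim_config(seed = 31, n_genes = 1,
                                    genome_length = 3000))
  g <- truth_genes(sim)[[1]]
  n <- nchar(sim$sequence)
  mirror <- function(iv) cbind(n - iv[, 2], n - iv[, 1])
  gm <- coding_gene(g$id, g$seqid, "-", exons = mirror(g$exons),
                    cds = c(n - g$cds[2], n - g$cds[1]),
                    sec_codons = g$sec_codons,
                    secis = mirror(g$secis),
                    secis_core = n - g$secis_core - 1L)
  rc <- selevo:::revcomp(sim$sequence)
  f1 <- gene_features(g, sim$sequence)
  f2 <- gene_features(gm, rc)
  expect_equal(f1$utr5_len, f2$utr5_len)
  expect_equal(f1$utr3_len, f2$utr3_len)
  expect_equal(f1$uga_to_secis$distance, f2$uga_to_secis$distance)
  expect_equal(f1$readthrough$ext_nt, f2$readthrough$ext_nt)
  expect_equal(f1$readthrough$ext_residues, f2$readthrough$ext_residues)
})

test_that("readthrough extension translates to the next in-frame stop", {
  mk <- function(utr3) {
    seq <- paste0("ATG", strrep("GCT", 5), "TAA", utr3)
    g <- coding_gene("r", "chr", "+",
                     exons = rbind(c(0L, nchar(seq))),
                     cds = c(0L, 21L))
    readthrough_extension(g, seq)
  }
  # 21 nt of extension -> 7 residues (the primate-style case)
  r <- mk(paste0(strrep("GCT", 7), "TAGAAA"))
  expect_equal(r$ext_nt, 21)
  expect_equal(nchar(r$ext_residues), 7)
  # 9 nt -> 3 residues
  r <- mk(paste0(strrep("GCT", 3), "TAACCC"))
  expect_equal(r$ext_nt, 9)
  expect_equal(nchar(r$ext_residues), 3)
  # stop immediately followed by an in-frame stop
  expect_equal(mk("TAGAA")$ext_nt, 0)
  # in-frame UGA is rendered as Sec and does not terminate
  r <- mk(paste0("TGA", strrep("GCT", 2), "TAA"))
  expect_equal(r$ext_nt, 9)
  expect_equal(r$ext_residues, "UAA")
  # no stop before the transcript end
  r <- mk(strrep("GCT", 4))
  expect_true(r$open_ended)
  expect_true(is.na(r$ext_nt))
})

test_that("Sec-site classification is total over the 64 codons", {
  bases <- c("A", "C", "G", "T")
  codons <- apply(expand.grid(bases, bases, bases), 1, paste, collapse = "")
  cls <- classify_sec_site(codons)
  expect_equal(sum(cls == "sec"), 1)       # TGA
  expect_equal(sum(cls == "cys"), 2)       # TGT, TGC
  expect_equal(sum(cls == "stop"), 2)      # TAA, TAG
  expect_equal(sum(startsWith(cls, "other(")), 59)
  expect_equal(classify_sec_site("TGA"), "sec")
  expect_equal(classify_sec_site("CGA"), "other(Arg)")
  expect_equal(classify_sec_site("TAG"), "stop")
  expect_error(classify_sec_site("TGX"), "ACGT")
})

test_that("pseudogene lesions are detected against an intact reference", {
  set.seed(302)
  ref <- random_cds(200)
  # ensure codon 161 is TGG so a single base creates TAG
  substr(ref, 161 * 3 - 2, 161 * 3) <- "TGG"
  cand <- ref
  substr(cand, 161 * 3 - 1, 161 * 3 - 1) <- "A"   # TGG -> TAG
  les <- detect_pseudogene_lesions(cand, ref)
  expect_equal(nrow(les), 1)
  expect_equal(les$type, "premature_stop")
  expect_equal(les$position, 161)
  # a six-base deletion is frame-preserving, not a frameshift
  cand2 <- paste0(substr(ref, 1, 33), substring(ref, 40))
  les2 <- detect_pseudogene_lesions(cand2, ref)
  expect_true(all(les2$type == "triplet_deletion"))
  expect_equal(sum(les2$length), -6)
  expect_false(any(les2$type == "frameshift"))
  # a single-base deletion is a frameshift
  cand3 <- paste0(substr(ref, 1, 90), substring(ref, 92))
  les3 <- detect_pseudogene_lesions(cand3, ref)
  expect_true("frameshift" %in% les3$type)
  # identical candidate -> no lesions; unrelated sequence -> coverage error
  expect_equal(nrow(detect_pseudogene_lesions(ref, ref)), 0)
  expect_error(detect_pseudogene_lesions(substr(ref, 1, 60), ref),
               "insufficient homology")
})

test_that("the Sec UGA aligned to the reference UGA is not a premature stop", {
  set.seed(303)
  ref <- random_cds(60)
  substr(ref, 90 - 2, 90) <- "TGA"    # Sec codon at position 30
  expect_equal(nrow(detect_pseudogene_lesions(ref, ref)), 0)
})
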