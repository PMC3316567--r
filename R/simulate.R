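# Seeded simulators: genomes with planted selenoprotein gene models, codon
# evolution at a fixed dN/dS (GY94-style rates, uniform codon frequencies),
# pseudogenization lesions, and amino-acid alignments evolved on a tree.
# Every simulator is a pure function of (configuration, seed).

#' Simulation configuration
#'
#' @param seed integer seed; fully determines all outputs.
#' @param genome_length genome length in nt.
#' @param n_genes number of selenoprotein gene models to plant.
#' @param secis_params SECIS grammar used for the planted elements.
#' @param utr5_len 5'-UTR length (nt) of planted genes.
#' @param cds_codons CDS length in codons (including start and stop).
#' @param sec_codon_index codon index (1-based within the CDS) that carries
#'   the in-frame UGA.
#' @param utr3_spacer nt between the stop codon and the SECIS element.
#' @param utr3_tail nt of 3'-UTR after the SECIS element.
#' @param intergenic_min minimum spacing between planted genes.
#' @return a list of class `sim_config`.
#' @export
sim_config <- function(seed = 1L, genome_length = 10000L, n_genes = 3L,
                       secis_params = selevo::secis_params(),
                       utr5_len = 60L, cds_codons = 100L,
                       sec_codon_index = 40L, utr3_spacer = 150L,
                       utr3_tail = 60L, intergenic_min = 100L) {
  stopifnot(seed == as.integer(seed), n_genes >= 0, genome_length > 0,
            sec_codon_index > 1, sec_codon_index < cds_codons)
  structure(as.list(environment()), class = "sim_config")
}

random_dna <- function(n) paste(sample(c("A", "C", "G", "T"), n, TRUE),
                                collapse = "")

# Random sense codons avoiding stops and (optionally) TGA-adjacent risk.
random_sense_codons <- function(n) {
  sense <- setdiff(sense_codons(), "TGA")
  paste(sample(sense, n, TRUE), collapse = "")
}

#' Simulate a genome with planted selenoprotein gene models
#'
#' Plants `n_genes` single-exon gene models, each with an in-frame TGA (Sec)
#' codon and a grammar-conformant SECIS element in its 3'-UTR, on a random
#' background; remaining space is random sequence.  Deterministic given the
#' configuration seed.
#'
#' @param config a [sim_config()] object.
#' @return list with `sequence` (character) and `truth` (data.frame of
#'   0-based half-open genomic coordinates per gene: gene, CDS, Sec codon,
#'   SECIS element and its core/apical anchors).
#' @export
simulate_genome <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(config$seed)
  p <- config
  genes <- vector("list", p$n_genes)
  truth <- list()
  cursor <- 0L
  pieces <- character()
  emit <- function(x) { pieces[[length(pieces) + 1L]] <<- x; cursor <<- cursor + nchar(x) }
  for (g in seq_len(p$n_genes)) {
    el <- generate_secis(p$secis_params, apical = sample(c("AA", "AA", "CC"), 1),
                         mismatches = sample(0:min(1, p$secis_params$helix2_max_mismatch), 1))
    n_mid <- p$cds_codons - 2L
    mid <- strsplit(random_sense_codons(n_mid), "")[[1]]
    mid <- paste(mid, collapse = "")
    substr(mid, (p$sec_codon_index - 2L) * 3L + 1L,
           (p$sec_codon_index - 2L) * 3L + 3L) <- "TGA"
    cds <- paste0("ATG", mid, "TAA")
    gene_seq <- paste0(random_dna(p$utr5_len), cds,
                       random_dna(p$utr3_spacer), el$seq,
                       random_dna(p$utr3_tail))
    gap <- p$intergenic_min + sample.int(p$intergenic_min, 1)
    if (cursor + gap + nchar(gene_seq) > p$genome_length)
      stop("planted features do not fit in genome_length (capacity error)")
    emit(random_dna(gap))
    gene_start <- cursor
    cds_start <- gene_start + p$utr5_len
    sec_start <- cds_start + (p$sec_codon_index - 1L) * 3L
    secis_start <- cds_start + 3L * p$cds_codons + p$utr3_spacer
    truth[[g]] <- data.frame(
      gene = sprintf("gene%02d", g), strand = "+",
      gene_start = gene_start, gene_end = gene_start + nchar(gene_seq),
      cds_start = cds_start, cds_end = cds_start + 3L * p$cds_codons,
      sec_start = sec_start, sec_end = sec_start + 3L,
      secis_start = secis_start, secis_end = secis_start + el$length,
      core5_start = secis_start + el$core5_start,
      core3_start = secis_start + el$core3_start,
      apical_start = secis_start + el$apical_start,
      stringsAsFactors = FALSE)
    emit(gene_seq)
  }
  if (cursor > p$genome_length)
    stop("planted features do not fit in genome_length (capacity error)")
  emit(random_dna(p$genome_length - cursor))
  truth <- if (length(truth)) do.call(rbind, truth) else
    data.frame(gene = character(), strand = character(),
               gene_start = integer(), gene_end = integer(),
               cds_start = integer(), cds_end = integer(),
               sec_start = integer(), sec_end = integer(),
               secis_start = integer(), secis_end = integer(),
               core5_start = integer(), core3_start = integer(),
               apical_start = integer(), stringsAsFactors = FALSE)
  list(sequence = paste(pieces, collapse = ""), truth = truth)
}

#' Apply pseudogenization lesions to a coding sequence
#'
#' Operators mirror the lesion types seen in mammalian selenoprotein
#' pseudogenes: `premature_stop` (a TGG codon becomes TAG by a single base
#' change; other codons are overwritten with TAG), `frameshift_indel`
#' (insertion of random bases or deletion of a length not divisible by 3),
#' `triplet_deletion` (frame-preserving removal of one codon) and
#' `secis_core_mutation` (the 3' core GA becomes GG).
#'
#' @param gene_cds coding (or gene) sequence.
#' @param lesion_ops list of lesions; each element is a list with `type` and
#'   `pos` (1-based codon index for codon-level ops, 1-based nt position
#'   otherwise) and optionally `len` (signed, for `frameshift_indel`;
#'   negative deletes).
#' @param seed integer seed (random bases of insertions).
#' @return the lesioned sequence, with the applied lesions (positions in
#'   the coordinates of the sequence at application time) in
#'   `attr(, "lesions")`.
#' @export
pseudogenize <- function(gene_cds, lesion_ops = list(), seed = 1L) {
  set.seed(seed)
  seq <- toupper(gene_cds)
  rec <- list()
  for (op in lesion_ops) {
    type <- op$type
    if (!type %in% c("frameshift_indel", "premature_stop",
                     "secis_core_mutation", "triplet_deletion"))
      stop("unknown lesion operator: ", type)
    if (type == "premature_stop") {
      i <- (op$pos - 1L) * 3L + 1L
      if (i + 2L > nchar(seq)) stop("lesion position outside sequence")
      substr(seq, i, i + 2L) <- "TAG"   # TGG -> TAG is a single-base change
      rec[[length(rec) + 1L]] <- data.frame(type = type, pos = op$pos, len = 0L)
    } else if (type == "triplet_deletion") {
      i <- (op$pos - 1L) * 3L + 1L
      if (i + 2L > nchar(seq)) stop("lesion position outside sequence")
      seq <- paste0(substr(seq, 1L, i - 1L), substring(seq, i + 3L))
      rec[[length(rec) + 1L]] <- data.frame(type = type, pos = op$pos, len = -3L)
    } else if (type == "frameshift_indel") {
      len <- if (is.null(op$len)) 1L else as.integer(op$len)
      if (len %% 3L == 0L) stop("frameshift_indel length must not be a multiple of 3")
      if (op$pos < 1L || op$pos > nchar(seq)) stop("lesion position outside sequence")
      if (len > 0) {
        seq <- paste0(substr(seq, 1L, op$pos - 1L), random_dna(len),
                      substring(seq, op$pos))
      } else {
        if (op$pos - len - 1L > nchar(seq)) stop("lesion position outside sequence")
        seq <- paste0(substr(seq, 1L, op$pos - 1L), substring(seq, op$pos - len))
      }
      rec[[length(rec) + 1L]] <- data.frame(type = type, pos = op$pos, len = len)
    } else {                        # secis_core_mutation: GA -> GG
      if (op$pos < 1L || op$pos + 1L > nchar(seq)) stop("lesion position outside sequence")
      if (substr(seq, op$pos, op$pos + 1L) != "GA")
        stop("no GA core at position ", op$pos)
      substr(seq, op$pos + 1L, op$pos + 1L) <- "G"
      rec[[length(rec) + 1L]] <- data.frame(type = type, pos = op$pos, len = 0L)
    }
  }
  attr(seq, "lesions") <- if (length(rec)) do.call(rbind, rec) else
    data.frame(type = character(), pos = integer(), len = integer())
  seq
}

# GY94-style codon rate matrix: single-nucleotide exchanges only, relative
# rate 1 for synonymous and `omega` for nonsynonymous changes, uniform codon
# frequencies, normalized to one expected substitution per codon site.
codon_rate_matrix <- function(omega) {
  stopifnot(omega >= 0)
  sense <- sense_codons()
  gc <- genetic_code()
  n <- length(sense)
  Q <- matrix(0, n, n, dimnames = list(sense, sense))
  split <- strsplit(sense, "")
  for (i in seq_len(n)) for (j in seq_len(n)) {
    if (i == j) next
    d <- split[[i]] != split[[j]]
    if (sum(d) != 1L) next
    Q[i, j] <- if (gc[sense[i]] == gc[sense[j]]) 1 else omega
  }
  diag(Q) <- -rowSums(Q)
  mu <- -mean(diag(Q))
  if (mu > 0) Q <- Q / mu
  Q
}

#' Evolve a coding sequence under a fixed dN/dS
#'
#' Continuous-time Markov codon evolution with single-nucleotide exchanges,
#' nonsynonymous rates scaled by `omega`, uniform codon frequencies and no
#' stop codons (never introduced).  `t` is the expected number of
#' substitutions per codon site.
#'
#' @param ancestor_cds sequence of sense codons (length divisible by 3, no
#'   internal stops).
#' @param omega dN/dS ratio (>= 0).
#' @param t branch length in expected substitutions per codon.
#' @param seed integer seed.
#' @return the descendant coding sequence.
#' @export
evolve_codons <- function(ancestor_cds, omega, t, seed = 1L) {
  stopifnot(t >= 0, omega >= 0)
  cods <- split_codons(ancestor_cds)
  if (any(!cods %in% sense_codons()))
    stop("ancestor contains stop codons or non-ACGT characters")
  if (t == 0) return(toupper(ancestor_cds))
  set.seed(seed)
  Q <- codon_rate_matrix(omega)
  e <- eigen(Q, symmetric = TRUE)    # symmetric under uniform frequencies
  P <- e$vectors %*% (exp(e$values * t) * t(e$vectors))
  P[P < 0] <- 0
  P <- P / rowSums(P)
  dimnames(P) <- dimnames(Q)
  idx <- match(cods, rownames(P))
  new_idx <- vapply(idx, function(i) sample.int(ncol(P), 1, prob = P[i, ]),
                    integer(1))
  paste(rownames(P)[new_idx], collapse = "")
}

#' Evolve an amino-acid alignment on a tree
#'
#' Sites are i.i.d.; the root sequence is drawn from the model's equilibrium
#' frequencies and propagated down every branch with the model's transition
#' probabilities.  Deterministic given the seed.
#'
#' @param tree `phylo` with branch lengths (substitutions/site).
#' @param model model name (one of the seven packaged empirical matrices,
#'   see [subst_model()]) or a `subst_model` object.
#' @param n_sites number of sites.
#' @param seed integer seed.
#' @return character matrix (tips x sites) of one-letter amino acids.
#' @export
evolve_aa_alignment <- function(tree, model, n_sites, seed = 1L) {
  if (is.character(model)) model <- subst_model(model)
  if (is.null(tree$edge.length)) stop("tree must have branch lengths")
  set.seed(seed)
  tree <- validate_species_tree(tree)
  ntip <- length(tree$tip.label)
  n_all <- ntip + tree$Nnode
  root <- tree_root(tree)
  seqs <- matrix(NA_integer_, n_all, n_sites)
  seqs[root, ] <- sample.int(20L, n_sites, TRUE, prob = model$freqs)
  ord <- rev(postorder_ids(tree))    # preorder
  edge_of <- match(seq_len(n_all), tree$edge[, 2])
  for (nd in setdiff(ord, root)) {
    P <- model_prob_matrix(model, tree$edge.length[edge_of[nd]])
    par <- tree$edge[edge_of[nd], 1]
    seqs[nd, ] <- vapply(seqs[par, ], function(a)
      sample.int(20L, 1, prob = P[a, ]), integer(1))
  }
  out <- matrix(.aa_alphabet[seqs[seq_len(ntip), , drop = FALSE]], ntip, n_sites)
  rownames(out) <- tree$tip.label
  out
}
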