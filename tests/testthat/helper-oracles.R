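# Shared fixtures and independent brute-force oracles used by the unit and
# property tests.  The oracles deliberately avoid the package's dynamic
# programming / pruning code paths.

random_named_tree <- function(n, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  tr <- ape::rtree(n)
  tr$tip.label <- paste0("t", seq_len(n))
  tr$node.label <- paste0("n", seq_len(tr$Nnode))
  tr
}

# Exhaustive-enumeration minimum Sankoff cost: try every assignment of
# residue states to the internal nodes of the birth clade.
oracle_sankoff_cost <- function(tree, states, cm, birth) {
  states <- states[tree$tip.label]
  b <- selevo:::node_id(tree, birth)
  ids <- selevo:::postorder_ids(tree, b)
  ntip <- length(tree$tip.label)
  internals <- ids[ids > ntip]
  tips <- ids[ids <= ntip]
  res <- c("sec", "cys", "other")
  par <- selevo:::tree_parents(tree)
  tip_choices <- lapply(tips, function(i) {
    if (states[i] %in% c("absent", "missing")) res else states[i]
  })
  best <- Inf
  grid_int <- if (length(internals))
    expand.grid(rep(list(res), length(internals)), stringsAsFactors = FALSE)
  else data.frame(.empty = 1)         # one row: nothing to assign
  grid_tip <- expand.grid(tip_choices, stringsAsFactors = FALSE)
  for (gi in seq_len(nrow(grid_int))) {
    lab <- character(ntip + tree$Nnode)
    if (length(internals)) lab[internals] <- unlist(grid_int[gi, ])
    for (ti in seq_len(nrow(grid_tip))) {
      lab[tips] <- unlist(grid_tip[ti, ])
      cost <- 0
      for (i in setdiff(ids, b)) {
        cost <- cost + cm[lab[par[i]], lab[i]]
        if (!is.finite(cost)) break
      }
      best <- min(best, cost)
    }
  }
  best
}

# Minimum number of loss branches consistent with Dollo presence: brute
# force over all subsets of branches inside the birth clade.
oracle_dollo_min_losses <- function(tree, states, birth) {
  states <- states[tree$tip.label]
  b <- selevo:::node_id(tree, birth)
  ids <- selevo:::postorder_ids(tree, b)
  ntip <- length(tree$tip.label)
  branches <- setdiff(ids, b)
  tipsets <- lapply(branches, function(i)
    selevo:::clade_tip_ids(tree, i))
  tips <- ids[ids <= ntip]
  absent <- tips[states[tips] == "absent"]
  present <- tips[!states[tips] %in% c("absent", "missing")]
  best <- Inf
  for (mask in 0:(2^length(branches) - 1)) {
    sel <- which(bitwAnd(mask, 2^(seq_along(branches) - 1)) > 0)
    covered <- unique(unlist(tipsets[sel]))
    if (all(absent %in% covered) && !any(present %in% covered))
      best <- min(best, length(sel))
  }
  best
}

# Brute-force pruning oracle: sum over all internal-node state assignments.
oracle_tree_loglik <- function(aln, tree, model) {
  idx <- selevo:::as_aa_matrix(aln)
  tree <- selevo:::validate_species_tree(tree)
  root <- selevo:::tree_root(tree)
  ntip <- length(tree$tip.label)
  n_all <- ntip + tree$Nnode
  internals <- setdiff(seq_len(n_all), seq_len(ntip))
  edge_of <- match(seq_len(n_all), tree$edge[, 2])
  P <- lapply(seq_len(n_all), function(nd)
    if (is.na(edge_of[nd])) NULL else
      selevo:::model_prob_matrix(model, tree$edge.length[edge_of[nd]]))
  idx <- idx[tree$tip.label, , drop = FALSE]
  tot <- 0
  for (site in seq_len(ncol(idx))) {
    grid <- expand.grid(rep(list(1:20), length(internals)))
    s <- 0
    for (r in seq_len(nrow(grid))) {
      a <- integer(n_all)
      a[internals] <- as.integer(grid[r, ])
      a[seq_len(ntip)] <- idx[, site]
      p <- unname(model$freqs[a[root]])
      for (e in seq_len(nrow(tree$edge)))
        p <- p * P[[tree$edge[e, 2]]][a[tree$edge[e, 1]], a[tree$edge[e, 2]]]
      s <- s + p
    }
    tot <- tot + log(s)
  }
  tot
}

# Non-overlapping dinucleotide shuffle (preserves the 2-mer multiset).
dinucleotide_shuffle <- function(seq) {
  n <- nchar(seq) - nchar(seq) %% 2
  dinucs <- substring(seq, seq(1, n, 2), seq(2, n, 2))
  paste0(paste(sample(dinucs), collapse = ""), substring(seq, n + 1))
}

random_cds <- function(n_codons) {
  paste(sample(setdiff(selevo:::sense_codons(), "TGA"), n_codons, TRUE),
        collapse = "")
}

# A toy two-exon gene on the plus strand with known geometry.
toy_gene <- function() {
  # exon1 [100,260): 10 nt 5'UTR + first 150 nt of CDS
  # exon2 [300,560): remaining 150 nt of CDS (incl stop) + 3'UTR with SECIS
  coding_gene(id = "toy", seqid = "chr", strand = "+",
              exons = rbind(c(100L, 260L), c(300L, 560L)),
              cds = c(110L, 450L),
              sec_codons = 30L,
              secis = rbind(c(480L, 540L)),
              secis_core = 486L)
}
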