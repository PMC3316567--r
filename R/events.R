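# Ancestral selenoproteome reconstruction: Dollo presence (single origin,
# losses allowed) for gene content, then Sankoff parsimony with an
# irreversibility constraint (no Cys/other -> Sec) for the residue state at
# the Sec position.  Branches are identified by the name of their child node.

#' Default residue transition cost matrix
#'
#' Unit cost for any change between `sec`, `cys` and `other`, except that
#' reversion to `sec` is forbidden (infinite cost): conversions of Cys back
#' to Sec are not observed in vertebrates.
#'
#' @return 3x3 numeric matrix over `sec`, `cys`, `other`.
#' @export
cost_matrix_default <- function() {
  cm <- matrix(1, 3, 3, dimnames = list(.residue_states, .residue_states))
  diag(cm) <- 0
  cm["cys", "sec"] <- Inf
  cm["other", "sec"] <- Inf
  cm
}

check_cost_matrix <- function(cm) {
  if (!all(rownames(cm) == .residue_states) || !all(colnames(cm) == .residue_states))
    stop("cost matrix must be over states sec, cys, other")
  if (any(diag(cm) != 0)) stop("cost matrix diagonal must be zero")
  if (any(cm < 0)) stop("costs must be nonnegative")
  cm
}

# Validate one family's tip states against a tree; returns named vector over
# all tips of the tree.
check_family_states <- function(tree, family_states) {
  if (is.null(names(family_states))) stop("family states must be named by taxon")
  miss <- setdiff(tree$tip.label, names(family_states))
  if (length(miss)) stop("no state for tips: ", paste(miss, collapse = ", "))
  s <- family_states[tree$tip.label]
  bad <- setdiff(unique(s), .selevo_states)
  if (length(bad)) stop("unknown states: ", paste(bad, collapse = ", "))
  s
}

#' Infer the birth branch of a gene family
#'
#' Under the single-origin (Dollo) assumption the family was born on the
#' branch above the most recent common ancestor of all tips where it is
#' observed (any state other than `absent`/`missing`); the branch is
#' identified by its child node, so a family observed across the root is
#' born "at the root".
#'
#' @param tree rooted `phylo` with named nodes.
#' @param family_states named character vector of phyletic states per tip.
#' @return the name of the birth node (child node of the birth branch).
#' @export
infer_birth_branch <- function(tree, family_states) {
  s <- check_family_states(tree, family_states)
  present <- names(s)[!s %in% c("absent", "missing")]
  if (!length(present))
    stop("family has no observed presence at any tip (no signal)")
  node_names(tree)[mrca_id(tree, present)]
}

#' Dollo loss branches of a family
#'
#' Returns every maximal branch inside the birth clade whose entire
#' descendant tip set is `absent` or `missing` with at least one `absent`
#' tip.  Subtrees that are missing-only emit no loss (absence of evidence is
#' not evidence of loss).
#'
#' @inheritParams infer_birth_branch
#' @param birth_branch name of the birth node, from [infer_birth_branch()].
#' @return character vector of loss branch (child node) names.
#' @export
dollo_losses <- function(tree, family_states, birth_branch) {
  s <- check_family_states(tree, family_states)
  b <- node_id(tree, birth_branch)
  ids <- postorder_ids(tree, b)
  ntip <- length(tree$tip.label)
  ch <- tree_children(tree)
  all_am <- any_abs <- logical(ntip + tree$Nnode)
  for (i in ids) {
    if (i <= ntip) {
      all_am[i] <- s[i] %in% c("absent", "missing")
      any_abs[i] <- s[i] == "absent"
    } else {
      all_am[i] <- all(all_am[ch[[i]]])
      any_abs[i] <- any(any_abs[ch[[i]]])
    }
  }
  lost <- function(i) all_am[i] && any_abs[i]
  par <- tree_parents(tree)
  loss_ids <- Filter(function(i) {
    lost(i) && (i == b || !lost(par[i]))
  }, ids)
  node_names(tree)[unlist(loss_ids)]
}

#' Sankoff ancestral residue states within a birth clade
#'
#' Minimum-cost labeling of every node of the birth clade with a residue
#' state in `sec`/`cys`/`other`, by dynamic programming up the tree followed
#' by a downward choice pass.  Tips with `absent` or `missing` states are
#' unconstrained (zero cost against any state) and ties are resolved toward
#' `sec`, then toward the parent's state.
#'
#' @inheritParams dollo_losses
#' @param cost_matrix residue transition costs, see [cost_matrix_default()].
#' @return list with `labels` (named character vector over the nodes of the
#'   birth clade) and `cost` (the minimum total cost).
#' @export
sankoff_states <- function(tree, family_states, cost_matrix = cost_matrix_default(),
                           birth_branch = infer_birth_branch(tree, family_states)) {
  s <- check_family_states(tree, family_states)
  cm <- check_cost_matrix(cost_matrix)
  b <- node_id(tree, birth_branch)
  ids <- postorder_ids(tree, b)
  ntip <- length(tree$tip.label)
  ch <- tree_children(tree)
  k <- length(.residue_states)
  C <- matrix(NA_real_, ntip + tree$Nnode, k)   # subtree min cost per state
  for (i in ids) {
    if (i <= ntip) {
      if (s[i] %in% c("absent", "missing")) C[i, ] <- 0
      else C[i, ] <- ifelse(.residue_states == s[i], 0, Inf)
    } else {
      C[i, ] <- 0
      for (cc in ch[[i]])
        C[i, ] <- C[i, ] + vapply(seq_len(k), function(a)
          min(cm[a, ] + C[cc, ]), numeric(1))
    }
  }
  total <- min(C[b, ])
  if (!is.finite(total)) stop("no feasible labeling under this cost matrix")
  pick <- function(scores, parent_state = NULL) {
    best <- which(scores == min(scores))
    pref <- c(match("sec", .residue_states),
              if (!is.null(parent_state)) match(parent_state, .residue_states),
              best)
    .residue_states[intersect(pref, best)[1L]]
  }
  lab <- rep(NA_character_, ntip + tree$Nnode)
  lab[b] <- pick(C[b, ])
  for (i in rev(ids)) {               # preorder
    if (i > ntip || length(ch[[i]])) {
      a <- match(lab[i], .residue_states)
      for (cc in ch[[i]])
        lab[cc] <- pick(cm[a, ] + C[cc, ], parent_state = lab[i])
    }
  }
  labels <- setNames(lab[ids], node_names(tree)[ids])
  list(labels = labels, cost = total)
}

#' Enumerate birth, loss and conversion events for a phyletic matrix
#'
#' Per family: one birth on the branch from [infer_birth_branch()]
#' (classified as a duplication when the metadata names a parent family and
#' the birth branch is below the root); losses from [dollo_losses()];
#' conversion events on every branch where the parent's reconstructed
#' residue state is `sec` and the child's is `cys` or `other`; plus one
#' conversion-at-birth for duplication-born families whose state at birth is
#' not `sec` while the parent family is reconstructed `sec` on the same
#' branch.
#'
#' @param tree rooted `phylo` with named nodes.
#' @param matrix a [presence_matrix()].
#' @param meta family metadata (defaults to the metadata attached to
#'   `matrix`); needs columns `family` and `parent_family`.
#' @param cost_matrix residue transition costs.
#' @return an `event_set`: a data.frame of events (`type`, `family`,
#'   `branch`, `from_state`, `to_state`, `duplication`) with the per-node
#'   ancestral state matrix in `attr(, "node_states")` and the tree in
#'   `attr(, "tree")`.
#' @export
enumerate_events <- function(tree, matrix, meta = family_meta(matrix),
                             cost_matrix = cost_matrix_default()) {
  tree <- validate_species_tree(tree)
  if (is.null(meta))
    meta <- data.frame(family = rownames(matrix), parent_family = "",
                       stringsAsFactors = FALSE)
  if (!all(rownames(matrix) %in% meta$family))
    stop("metadata missing families: ",
         paste(setdiff(rownames(matrix), meta$family), collapse = ", "))
  unknown <- setdiff(setdiff(meta$parent_family, ""), meta$family)
  if (length(unknown))
    stop("parent_family references unknown families: ",
         paste(unknown, collapse = ", "))
  nn <- node_names(tree)
  ntip <- length(tree$tip.label)
  root <- nn[tree_root(tree)]
  par <- tree_parents(tree)
  m <- unclass(matrix)

  node_states <- base::matrix("absent", nrow(m), length(nn),
                              dimnames = list(rownames(m), nn))
  recon <- vector("list", nrow(m))
  names(recon) <- rownames(m)
  ev <- list()
  add <- function(type, family, branch, from, to, dup = FALSE)
    ev[[length(ev) + 1L]] <<- data.frame(type = type, family = family,
                                         branch = branch, from_state = from,
                                         to_state = to, duplication = dup,
                                         stringsAsFactors = FALSE)

  for (f in rownames(m)) {
    st <- m[f, ]
    birth <- infer_birth_branch(tree, st)
    losses <- dollo_losses(tree, st, birth)
    sk <- sankoff_states(tree, st, cost_matrix, birth)
    lab <- sk$labels
    # Presence layer: nodes of the birth clade minus lost subtrees.
    clade <- names(lab)
    lost_ids <- unlist(lapply(losses, function(l)
      clade_ids(tree, node_id(tree, l))))
    present <- setdiff(clade, nn[lost_ids])
    ns <- node_states[f, ]
    ns[present] <- lab[present]
    tips <- intersect(nn[seq_len(ntip)], clade)
    ns[tips] <- st[tips]               # tips keep their observed state
    node_states[f, ] <- ns
    recon[[f]] <- list(birth = birth, losses = losses, labels = lab,
                       cost = sk$cost, present = present)

    pf <- meta$parent_family[match(f, meta$family)]
    dup <- nzchar(pf) && birth != root
    add("birth", f, birth, NA_character_, lab[birth], dup)
    for (l in losses) {
      from <- lab[nn[par[node_id(tree, l)]]]
      if (node_id(tree, l) == node_id(tree, birth)) from <- lab[birth]
      add("loss", f, l, from, "absent")
    }
    # Conversions on branches internal to the present part of the clade.
    for (nd in setdiff(present, birth)) {
      p <- nn[par[node_id(tree, nd)]]
      if (p %in% present && lab[p] == "sec" && lab[nd] %in% c("cys", "other"))
        add("conversion", f, nd, "sec", lab[nd])
    }
  }
  # Conversion-at-birth for duplication-born families not born in sec state.
  for (f in rownames(m)) {
    pf <- meta$parent_family[match(f, meta$family)]
    if (!nzchar(pf)) next
    birth <- recon[[f]]$birth
    b_state <- recon[[f]]$labels[birth]
    parent_state <- node_states[pf, birth]
    if (b_state != "sec" && parent_state == "sec")
      add("conversion", f, birth, "sec", b_state)
  }
  events <- do.call(rbind, ev)
  rownames(events) <- NULL
  bad <- events$type == "conversion" & events$to_state == "sec"
  if (any(bad)) stop("internal error: conversion to sec reconstructed")
  structure(events, class = c("event_set", "data.frame"),
            node_states = node_states, tree = tree, reconstruction = recon)
}

#' @export
print.event_set <- function(x, ...) {
  s <- summary(x)
  cat("event_set:", nrow(x), "events over", s[["n_families"]], "families\n")
  print(s)
  invisible(x)
}

#' Event counts of an event set
#'
#' @param object an `event_set`.
#' @param ... unused.
#' @return named integer vector: families, births, duplication births,
#'   losses, Sec-to-Cys conversions, Sec-to-other replacements, and total
#'   conversion-type events.
#' @export
summary.event_set <- function(object, ...) {
  ev <- as.data.frame(object)
  c(n_families = length(unique(ev$family)),
    n_births = sum(ev$type == "birth"),
    n_duplications = sum(ev$type == "birth" & ev$duplication),
    n_losses = sum(ev$type == "loss"),
    n_conversions_to_cys = sum(ev$type == "conversion" & ev$to_state == "cys"),
    n_conversions_to_other = sum(ev$type == "conversion" & ev$to_state == "other"),
    n_conversions_total = sum(ev$type == "conversion"))
}

#' Restrict events to a clade
#'
#' Keeps events whose branch lies within the subtree that descends from (and
#' includes the stem branch of) `node`.
#'
#' @param events an `event_set`.
#' @param node internal node (or tip) name.
#' @return the filtered `event_set`.
#' @export
events_in_clade <- function(events, node) {
  tree <- attr(events, "tree")
  keep <- node_names(tree)[clade_ids(tree, node_id(tree, node))]
  out <- events[events$branch %in% keep, , drop = FALSE]
  attributes(out)[c("node_states", "tree", "reconstruction")] <-
    attributes(events)[c("node_states", "tree", "reconstruction")]
  class(out) <- class(events)
  out
}

#' Ancestral selenoproteome at a node
#'
#' Families whose reconstructed state at `node` is `sec`.  At a tip this
#' equals the set of families observed in the `sec` state at that tip.
#'
#' @param events an `event_set` from [enumerate_events()].
#' @param node node name (internal or tip).
#' @return character vector of family names.
#' @export
ancestral_selenoproteome <- function(events, node) {
  ns <- attr(events, "node_states")
  if (!node %in% colnames(ns)) stop("unknown node name: ", node)
  rownames(ns)[ns[, node] == "sec"]
}

#' @export
selenoproteome_size.event_set <- function(x, taxon) {
  tree <- attr(x, "tree")
  if (!taxon %in% tree$tip.label) stop("unknown taxon: ", taxon)
  length(ancestral_selenoproteome(x, taxon))
}

#' Write an event set to TSV
#'
#' @param events an `event_set`.
#' @param path output TSV path.
#' @return `path`, invisibly.
#' @export
write_events <- function(events, path) {
  utils::write.table(as.data.frame(events), path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
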