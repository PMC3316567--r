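# Internal helpers over ape "phylo" trees.  Nodes are addressed by name;
# every node (tip or internal) must carry a unique name.  Traversals work on
# the edge matrix directly so multifurcations and degree-2 (pass-through)
# nodes are handled uniformly.

#' Read and validate a rooted species tree
#'
#' Reads a newick file with [ape::read.tree()].  Internal nodes without a
#' label are assigned stable names (`node<k>`); duplicate names are an error.
#'
#' @param path path to a newick file.
#' @return an object of class `phylo` with unique tip and node labels.
#' @export
read_newick <- function(path) {
  tr <- ape::read.tree(path)
  if (is.null(tr)) stop("could not parse newick file: ", path)
  validate_species_tree(tr)
}

#' Write a tree to newick
#'
#' @param tree a `phylo` object.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_newick <- function(tree, path) {
  ape::write.tree(tree, file = path)
  invisible(path)
}

#' Validate (and repair labels of) a rooted species tree
#'
#' @param tree a `phylo` object.
#' @return the tree, with unnamed internal nodes given `node<k>` labels.
#' @export
validate_species_tree <- function(tree) {
  if (!inherits(tree, "phylo")) stop("not a phylo object")
  if (is.null(tree$node.label)) tree$node.label <- rep("", tree$Nnode)
  blank <- !nzchar(tree$node.label)
  tree$node.label[blank] <- paste0("node", which(blank))
  labs <- c(tree$tip.label, tree$node.label)
  if (anyDuplicated(labs))
    stop("duplicate node names in tree: ",
         paste(unique(labs[duplicated(labs)]), collapse = ", "))
  tree
}

# All node names indexed by ape node id (tips first, then internals).
node_names <- function(tree) {
  tree <- validate_species_tree(tree)
  c(tree$tip.label, tree$node.label)
}

node_id <- function(tree, name) {
  id <- match(name, node_names(tree))
  if (anyNA(id)) stop("unknown node name: ",
                      paste(name[is.na(id)], collapse = ", "))
  id
}

tree_root <- function(tree) {
  n <- length(tree$tip.label)
  cand <- setdiff(tree$edge[, 1], tree$edge[, 2])
  if (length(unique(cand)) != 1L) stop("tree must have exactly one root")
  as.integer(unique(cand))
}

# children[[id]]: integer vector of child node ids (empty for tips).
tree_children <- function(tree) {
  n_all <- length(tree$tip.label) + tree$Nnode
  ch <- vector("list", n_all)
  for (i in seq_len(nrow(tree$edge)))
    ch[[tree$edge[i, 1]]] <- c(ch[[tree$edge[i, 1]]], tree$edge[i, 2])
  ch
}

# parent[id]: parent node id (NA for the root).
tree_parents <- function(tree) {
  n_all <- length(tree$tip.label) + tree$Nnode
  par <- rep(NA_integer_, n_all)
  par[tree$edge[, 2]] <- tree$edge[, 1]
  par
}

# Postorder of node ids of the subtree rooted at `node` (children first).
postorder_ids <- function(tree, node = tree_root(tree)) {
  ch <- tree_children(tree)
  out <- integer(0)
  stack <- node
  seen <- integer(0)
  while (length(stack)) {            # iterative DFS, emit in reverse
    cur <- stack[length(stack)]
    stack <- stack[-length(stack)]
    seen <- c(seen, cur)
    stack <- c(stack, ch[[cur]])
  }
  rev(seen)
}

# All node ids in the clade rooted at `node` (including `node`).
clade_ids <- function(tree, node) postorder_ids(tree, node)

# Tip ids under `node`.
clade_tip_ids <- function(tree, node) {
  ids <- clade_ids(tree, node)
  ids[ids <= length(tree$tip.label)]
}

# MRCA id of a set of tip names (the tip itself for a single tip).
mrca_id <- function(tree, tips) {
  ids <- node_id(tree, tips)
  if (length(ids) == 1L) return(ids)
  par <- tree_parents(tree)
  path_to_root <- function(i) {
    p <- i
    while (!is.na(par[i])) { i <- par[i]; p <- c(p, i) }
    p
  }
  common <- Reduce(intersect, lapply(ids, path_to_root))
  common[1L]
}
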