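# Model-selection phylogenetics: BioNJ starting topology, fixed-topology
# likelihood under seven empirical amino-acid replacement models
# (Felsenstein pruning, authored here; phangorn only supplies the published
# exchangeability matrices), AIC model ranking, NNI hill-climbing, and aLRT
# branch support from the chi-square mixture.

.aa_alphabet <- c("A", "R", "N", "D", "C", "Q", "E", "G", "H", "I",
                  "L", "K", "M", "F", "P", "S", "T", "W", "Y", "V")

.supported_models <- c("JTT", "LG", "WAG", "Blosum62", "MtREV", "VT", "Dayhoff")

#' Empirical amino-acid substitution model
#'
#' Builds the reversible rate matrix of one of the seven supported
#' empirical models (JTT, LG, WAG, Blosum62, MtREV, VT, Dayhoff) from its
#' published exchangeabilities and equilibrium frequencies, normalized to
#' one expected substitution per site, with the spectral decomposition
#' cached for fast transition probabilities.
#'
#' @param name model name.
#' @return an object of class `subst_model`: list with `name`, `S`
#'   (symmetric exchangeability matrix), `freqs`, `Q` (scaled rate matrix)
#'   and the cached eigendecomposition.
#' @export
subst_model <- function(name) {
  name <- match.arg(name, .supported_models)
  phname <- if (name == "MtREV") "mtREV24" else name
  raw <- tryCatch(get(paste0(".", phname), envir = environment(phangorn::pml)),
                  error = function(e) stop("cannot retrieve model ", name))
  S <- matrix(0, 20, 20, dimnames = list(.aa_alphabet, .aa_alphabet))
  S[lower.tri(S)] <- raw$Q
  S <- S + t(S)
  freqs <- as.numeric(raw$bf)
  freqs <- freqs / sum(freqs)
  names(freqs) <- .aa_alphabet
  Q <- S * rep(freqs, each = 20)
  diag(Q) <- -rowSums(Q)
  mu <- -sum(freqs * diag(Q))
  Q <- Q / mu
  # Spectral decomposition in the pi-symmetrized basis.
  sq <- sqrt(freqs)
  B <- Q * outer(sq, 1 / sq)
  e <- eigen((B + t(B)) / 2, symmetric = TRUE)
  U <- e$vectors / sq               # rows scaled by 1/sqrt(pi)
  W <- t(e$vectors * sq)            # columns scaled by sqrt(pi), transposed
  structure(list(name = name, S = S, freqs = freqs, Q = Q,
                 eig = list(values = e$values, U = U, W = W)),
            class = "subst_model")
}

# P(t) = U diag(exp(lambda t)) W, clamped to [0, 1] row-stochastic.
model_prob_matrix <- function(model, t) {
  e <- model$eig
  P <- e$U %*% (exp(e$values * t) * e$W)
  P[P < 0] <- 0
  P / rowSums(P)
}

# ---- alignments ------------------------------------------------------------

# Accepts a tips x sites character matrix or named character vector of
# strings; returns an integer matrix (0 = missing/gap/ambiguity).
as_aa_matrix <- function(alignment) {
  if (is.character(alignment) && !is.matrix(alignment)) {
    if (is.null(names(alignment))) stop("alignment sequences must be named")
    if (length(unique(nchar(alignment))) != 1)
      stop("alignment sequences must have equal length")
    alignment <- do.call(rbind, strsplit(toupper(alignment), ""))
  }
  idx <- matrix(match(toupper(alignment), .aa_alphabet),
                nrow(alignment), ncol(alignment))
  idx[is.na(idx)] <- 0L
  rownames(idx) <- rownames(alignment)
  idx
}

# Site-pattern compression: unique columns + weights.
compress_patterns <- function(idx) {
  key <- apply(idx, 2, paste, collapse = ",")
  u <- !duplicated(key)
  list(patterns = idx[, u, drop = FALSE],
       weights = as.numeric(table(key)[key[u]]))
}

# ---- pruning likelihood ----------------------------------------------------

# Log-likelihood of an alignment on a tree (edge lengths in `lens`,
# indexed by edge row).  Reversible model => rooting is irrelevant.
prune_loglik <- function(tree, lens, comp, model) {
  pat <- comp$patterns
  npat <- ncol(pat)
  ntip <- length(tree$tip.label)
  ch <- tree_children(tree)
  edge_of <- match(seq_len(ntip + tree$Nnode), tree$edge[, 2])
  ids <- postorder_ids(tree)
  tipmap <- match(tree$tip.label, rownames(pat))
  L <- vector("list", ntip + tree$Nnode)
  scale_log <- 0
  for (nd in ids) {
    if (nd <= ntip) {
      M <- matrix(0, 20, npat)
      s <- pat[tipmap[nd], ]
      M[cbind(s[s > 0], which(s > 0))] <- 1
      M[, s == 0] <- 1               # gap/ambiguity: fully missing
      L[[nd]] <- M
    } else {
      M <- matrix(1, 20, npat)
      for (cc in ch[[nd]]) {
        P <- model_prob_matrix(model, lens[edge_of[cc]])
        M <- M * (P %*% L[[cc]])
      }
      mx <- apply(M, 2, max)
      mx[mx == 0] <- 1
      scale_log <- scale_log + sum(comp$weights * log(mx))
      L[[nd]] <- M / rep(mx, each = 20)
    }
  }
  root <- tree_root(tree)
  site <- colSums(model$freqs * L[[root]])
  sum(comp$weights * log(site)) + scale_log
}

# Up/down message passing: L[[v]] = partial likelihood of the subtree below
# v (at v); O[[v]] = partial likelihood of everything outside v's subtree,
# as a function of the state of v's parent (equilibrium frequencies enter at
# the root).  Per-pattern log scale factors accompany both.  With these, the
# likelihood as a function of a single branch length costs one transition
# matrix: sum_pat w * log colSums(O[[v]] * (P(t) %*% L[[v]])).
tree_messages <- function(tree, lens, comp, model) {
  pat <- comp$patterns
  npat <- ncol(pat)
  ntip <- length(tree$tip.label)
  n_all <- ntip + tree$Nnode
  ch <- tree_children(tree)
  edge_of <- match(seq_len(n_all), tree$edge[, 2])
  tipmap <- match(tree$tip.label, rownames(pat))
  P <- vector("list", n_all)
  for (nd in seq_len(n_all))
    if (!is.na(edge_of[nd]))
      P[[nd]] <- model_prob_matrix(model, lens[edge_of[nd]])
  L <- Lmsg <- O <- vector("list", n_all)
  sL <- sO <- vector("list", n_all)
  for (nd in postorder_ids(tree)) {
    if (nd <= ntip) {
      M <- matrix(0, 20, npat)
      s <- pat[tipmap[nd], ]
      M[cbind(s[s > 0], which(s > 0))] <- 1
      M[, s == 0] <- 1
      L[[nd]] <- M; sL[[nd]] <- numeric(npat)
    } else {
      M <- matrix(1, 20, npat); sc <- numeric(npat)
      for (cc in ch[[nd]]) {
        M <- M * (P[[cc]] %*% L[[cc]])
        sc <- sc + sL[[cc]]
      }
      mx <- apply(M, 2, max); mx[mx == 0] <- 1
      L[[nd]] <- M / rep(mx, each = 20); sL[[nd]] <- sc + log(mx)
    }
    if (!is.na(edge_of[nd])) Lmsg[[nd]] <- P[[nd]] %*% L[[nd]]
  }
  root <- tree_root(tree)
  for (nd in rev(postorder_ids(tree))) {     # preorder
    kids <- ch[[nd]]
    if (!length(kids)) next
    base <- if (nd == root) matrix(model$freqs, 20, npat) else
      crossprod(P[[nd]], O[[nd]])
    sbase <- if (nd == root) numeric(npat) else sO[[nd]]
    for (w in kids) {
      M <- base; sc <- sbase
      for (cc in setdiff(kids, w)) {
        M <- M * Lmsg[[cc]]
        sc <- sc + sL[[cc]]
      }
      mx <- apply(M, 2, max); mx[mx == 0] <- 1
      O[[w]] <- M / rep(mx, each = 20); sO[[w]] <- sc + log(mx)
    }
  }
  list(L = L, O = O, sL = sL, sO = sO)
}

edge_loglik <- function(msg, v, P, weights) {
  s <- colSums(msg$O[[v]] * (P %*% msg$L[[v]]))
  sum(weights * (log(s) + msg$sL[[v]] + msg$sO[[v]]))
}

#' Fixed-topology log-likelihood under an empirical model
#'
#' Felsenstein pruning log-likelihood of an amino-acid alignment on a fixed
#' tree topology, with gaps and ambiguity codes treated as missing, and
#' optional branch-length optimization by iterated one-dimensional
#' (bracketed) search per branch until the per-sweep likelihood gain drops
#' below `logl_tol`.
#'
#' @param alignment tips x sites character matrix or named character vector.
#' @param tree `phylo`; tip labels must match the alignment names.
#' @param model a [subst_model()] or model name.
#' @param optimize optimize branch lengths (default `TRUE`).
#' @param logl_tol per-sweep log-likelihood convergence tolerance.
#' @param bl_tol branch-length search tolerance.
#' @param max_bl upper bound for a single branch length.
#' @param max_sweeps cap on optimization sweeps.
#' @return an object of class `likelihood_result`: list with `tree`
#'   (optimized branch lengths), `logL`, `model`, `n_parameters` (number of
#'   free branch lengths; the empirical matrices contribute none).
#' @export
fixed_topology_loglik <- function(alignment, tree, model,
                                  optimize = TRUE, logl_tol = 1e-6,
                                  bl_tol = 1e-8, max_bl = 50,
                                  max_sweeps = 20L) {
  if (is.character(model)) model <- subst_model(model)
  tree <- validate_species_tree(tree)
  idx <- as_aa_matrix(alignment)
  if (!setequal(rownames(idx), tree$tip.label))
    stop("alignment taxa do not match tree tips")
  comp <- compress_patterns(idx)
  if (is.null(tree$edge.length)) tree$edge.length <- rep(0.1, nrow(tree$edge))
  lens <- pmax(tree$edge.length, 1e-8)
  ll <- prune_loglik(tree, lens, comp, model)
  if (optimize && ncol(idx) > 0) {
    for (sweep in seq_len(max_sweeps)) {
      before <- ll
      msg <- tree_messages(tree, lens, comp, model)
      for (ei in seq_len(nrow(tree$edge))) {
        v <- tree$edge[ei, 2]
        f <- function(x) edge_loglik(msg, v, model_prob_matrix(model, x),
                                     comp$weights)
        opt <- stats::optimize(f, c(0, max_bl), maximum = TRUE, tol = bl_tol)
        # messages go stale within a sweep; accept only exact improvements
        lens2 <- lens; lens2[ei] <- opt$maximum
        ll2 <- prune_loglik(tree, lens2, comp, model)
        if (ll2 > ll) { lens <- lens2; ll <- ll2 }
      }
      if (ll - before < logl_tol) break
    }
  }
  tree$edge.length <- lens
  structure(list(tree = tree, logL = ll, model = model$name,
                 n_parameters = nrow(tree$edge)),
            class = "likelihood_result")
}

#' @export
print.likelihood_result <- function(x, ...) {
  cat(sprintf("logL = %.6f under %s (%d branch lengths)\n",
              x$logL, x$model, x$n_parameters))
  invisible(x)
}

#' AIC ranking of substitution models on a fixed topology
#'
#' Fits every model with branch-length optimization on the same topology
#' and ranks them by AIC = 2k - 2 logL, where k counts the free branch
#' lengths (the empirical matrices contribute no free parameters).  The two
#' best-fitting models are flagged for the subsequent ML tree search.
#'
#' @inheritParams fixed_topology_loglik
#' @param models character vector of model names (>= 2).
#' @param ... passed to [fixed_topology_loglik()].
#' @return data.frame of class `aic_table` with columns `model`, `logL`,
#'   `k`, `AIC`, `delta_AIC`, `rank`, `top2`, sorted by AIC.
#' @export
aic_rank <- function(alignment, tree, models = .supported_models, ...) {
  if (length(models) < 2) stop("need at least two models to rank")
  fits <- lapply(models, function(m)
    fixed_topology_loglik(alignment, tree, m, ...))
  tab <- data.frame(model = models,
                    logL = vapply(fits, `[[`, numeric(1), "logL"),
                    k = vapply(fits, `[[`, numeric(1), "n_parameters"))
  tab$AIC <- 2 * tab$k - 2 * tab$logL
  tab <- tab[order(tab$AIC), , drop = FALSE]
  tab$delta_AIC <- tab$AIC - tab$AIC[1]
  tab$rank <- rank(tab$AIC, ties.method = "min")
  tab$top2 <- tab$rank <= 2
  rownames(tab) <- NULL
  structure(tab, class = c("aic_table", "data.frame"), fits = fits)
}

# ---- BioNJ -----------------------------------------------------------------

#' BioNJ tree from a distance matrix
#'
#' Variance-weighted neighbour joining (BioNJ, via [ape::bionj()]); input is
#' validated and the two-taxon case (a single branch split at its midpoint)
#' is handled directly.  For additive distances the tree reproduces the
#' matrix exactly.
#'
#' @param d symmetric nonnegative distance matrix (or `dist`).
#' @return unrooted `phylo`.
#' @export
bionj_tree <- function(d) {
  d <- as.matrix(d)
  if (nrow(d) != ncol(d) || any(abs(d - t(d)) > 1e-12))
    stop("distance matrix must be symmetric")
  if (any(diag(d) != 0)) stop("distance matrix diagonal must be zero")
  if (any(d < 0)) stop("distances must be nonnegative")
  if (nrow(d) < 2) stop("need at least two taxa")
  if (is.null(rownames(d))) rownames(d) <- colnames(d) <- paste0("t", seq_len(nrow(d)))
  if (nrow(d) == 2) {
    tr <- list(edge = matrix(c(3L, 3L, 1L, 2L), 2, 2),
               edge.length = rep(d[1, 2] / 2, 2),
               tip.label = rownames(d), Nnode = 1L)
    class(tr) <- "phylo"
    return(tr)
  }
  ape::bionj(as.dist(d))
}

# Poisson-corrected (20-state Jukes-Cantor) pairwise distances.
aa_distance_matrix <- function(alignment) {
  idx <- as_aa_matrix(alignment)
  n <- nrow(idx)
  d <- matrix(0, n, n, dimnames = list(rownames(idx), rownames(idx)))
  for (i in seq_len(n - 1)) for (j in (i + 1):n) {
    ok <- idx[i, ] > 0 & idx[j, ] > 0
    p <- if (any(ok)) mean(idx[i, ok] != idx[j, ok]) else 0
    p <- min(p, 0.94)               # cap below the 19/20 saturation point
    d[i, j] <- d[j, i] <- -19 / 20 * log(1 - 20 / 19 * p)
  }
  d
}

# ---- NNI and aLRT ----------------------------------------------------------

# The two NNI rearrangements around the internal branch above `child`:
# swap each child subtree of `child` with a sibling subtree.
nni_neighbors_edge <- function(tree, child) {
  ntip <- length(tree$tip.label)
  par <- tree_parents(tree)
  ch <- tree_children(tree)
  v <- child
  if (v <= ntip) stop("aLRT/NNI needs an internal branch (terminal given)")
  u <- par[v]
  if (is.na(u)) stop("the root has no stem branch")
  kids <- ch[[v]]
  root <- tree_root(tree)
  if (u == root && length(ch[[u]]) == 2) {
    # In a rooted binary tree the two root edges form a single unrooted
    # edge; NNI exchanges a child of v with a child of its sibling.
    sib <- setdiff(ch[[u]], v)
    if (sib <= ntip)
      stop("aLRT/NNI needs an internal branch (terminal given)")
    sibkids <- ch[[sib]]
    return(lapply(sibkids[1:2], function(s) {
      t2 <- tree
      t2$edge[which(t2$edge[, 2] == kids[2]), 1] <- sib
      t2$edge[which(t2$edge[, 2] == s), 1] <- v
      t2
    }))
  }
  sib <- setdiff(ch[[u]], v)[1]
  lapply(kids[1:2], function(a) {
    t2 <- tree
    t2$edge[which(t2$edge[, 2] == a), 1] <- u
    t2$edge[which(t2$edge[, 2] == sib), 1] <- v
    t2
  })
}

internal_branches <- function(tree) {
  ntip <- length(tree$tip.label)
  root <- tree_root(tree)
  setdiff(tree$edge[, 2][tree$edge[, 2] > ntip], root)
}

#' NNI hill-climbing tree search
#'
#' Explores all nearest-neighbour-interchange rearrangements of the current
#' tree, accepts the best strictly improving neighbour (branch lengths
#' re-optimized for every candidate), and stops when no neighbour improves
#' the log-likelihood.
#'
#' @inheritParams fixed_topology_loglik
#' @param start_tree binary starting tree.
#' @param ... passed to [fixed_topology_loglik()].
#' @return a `likelihood_result` with the final tree; its log-likelihood is
#'   never below the starting tree's.
#' @export
nni_search <- function(alignment, start_tree, model, ...) {
  if (is.character(model)) model <- subst_model(model)
  cur <- fixed_topology_loglik(alignment, start_tree, model, ...)
  repeat {
    improved <- FALSE
    best <- cur
    for (v in internal_branches(cur$tree)) {
      for (t2 in nni_neighbors_edge(cur$tree, v)) {
        fit <- fixed_topology_loglik(alignment, t2, model, ...)
        if (fit$logL > best$logL + 1e-9) { best <- fit; improved <- TRUE }
      }
    }
    if (!improved) break
    cur <- best
  }
  cur
}

#' aLRT branch support
#'
#' Approximate likelihood-ratio test for an internal branch: the statistic
#' is twice the log-likelihood difference between the best and second-best
#' of the three NNI configurations around the branch, and support is the
#' CDF of the 1/2 chi-square(0) + 1/2 chi-square(1) mixture at the
#' statistic (0.5 at a statistic of zero; 0 when the current topology is
#' not the best configuration).
#'
#' @inheritParams fixed_topology_loglik
#' @param branch internal node name (or id) identifying the branch above it.
#' @param ... passed to [fixed_topology_loglik()].
#' @return list with `support`, `statistic`, and the three per-configuration
#'   log-likelihoods.
#' @export
alrt_support <- function(alignment, tree, model, branch, ...) {
  if (is.character(model)) model <- subst_model(model)
  tree <- validate_species_tree(tree)
  v <- if (is.character(branch)) node_id(tree, branch) else as.integer(branch)
  fit0 <- fixed_topology_loglik(alignment, tree, model, ...)
  alts <- nni_neighbors_edge(fit0$tree, v)
  ll <- c(fit0$logL, vapply(alts, function(t2)
    fixed_topology_loglik(alignment, t2, model, ...)$logL, numeric(1)))
  stat <- 2 * (ll[1] - max(ll[2:3]))
  support <- if (stat < 0) 0 else 0.5 + 0.5 * stats::pchisq(stat, df = 1)
  list(support = support, statistic = stat, logL = ll)
}

#' Best-model ML workflow
#'
#' The full phylogenetic procedure: BioNJ starting topology from
#' Poisson-corrected distances, AIC model ranking on that fixed topology,
#' NNI search under the two best models, and aLRT support on the internal
#' branches of the winning tree.
#'
#' @param alignment tips x sites character matrix or named character vector.
#' @param models candidate model names.
#' @param support compute aLRT supports for the final tree.
#' @param ... passed to [fixed_topology_loglik()].
#' @return list with `start_tree`, `aic` (an `aic_table`), `fits` (NNI
#'   results for the two best models), `best` (the winning
#'   `likelihood_result`) and `alrt` (per-branch supports or `NULL`).
#' @export
bestml <- function(alignment, models = .supported_models, support = TRUE, ...) {
  start <- bionj_tree(aa_distance_matrix(alignment))
  aic <- aic_rank(alignment, start, models, ...)
  top2 <- aic$model[aic$top2][1:2]
  fits <- lapply(top2, function(m) nni_search(alignment, start, m, ...))
  names(fits) <- top2
  best <- fits[[which.max(vapply(fits, `[[`, numeric(1), "logL"))]]
  alrt <- NULL
  if (support) {
    br <- internal_branches(best$tree)
    alrt <- data.frame(
      branch = node_names(best$tree)[br],
      support = vapply(br, function(v)
        alrt_support(alignment, best$tree, best$model, v, ...)$support,
        numeric(1)))
  }
  list(start_tree = start, aic = aic, fits = fits, best = best, alrt = alrt)
}
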