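#' Load the packaged vertebrate selenoproteome fixture
#'
#' The fixture transcribes the group-level presence table of the vertebrate
#' selenoproteome survey into tip-level phyletic states on a 24-taxon rooted
#' species tree with named internal nodes (`Vertebrata`, `Mammalia`,
#' `Theria`, `Placentalia`, `Percomorpha`, ...).  It contains the 45
#' selenoprotein subfamilies plus the three Cys-only duplicates (GPx5,
#' GPx4b2, Rdx12) whose Sec-to-Cys conversion happened at birth.  Group-level
#' presences are encoded as `sec` at the member tips; depicted conversions as
#' `cys` (or `other` for the pufferfish SelW2c arginine form); table blanks
#' not explained by a depicted loss or conversion as `missing`.
#'
#' @return a list of class `paper_fixture` with elements `tree` (a `phylo`),
#'   `matrix` (a [presence_matrix()] with attached metadata), `meta` (the
#'   family metadata data.frame) and `groups` (named list mapping the six
#'   taxon groups of the presence table to fixture tips).
#' @export
load_paper_fixture <- function() {
  path <- function(f) system.file("extdata", f, package = "selevo", mustWork = TRUE)
  tree <- read_newick(path("selevo_tree.nwk"))
  meta <- read_family_meta(path("selevo_family_meta.tsv"))
  mat <- read_state_matrix(path("selevo_states.tsv"), meta = meta)
  groups <- list(
    fish = c("elephant_shark", "zebrafish", "medaka", "stickleback",
             "fugu", "pufferfish"),
    frog = "frog",
    birds = c("chicken", "zebra_finch"),
    platypus = "platypus",
    marsupials = c("opossum", "wallaby"),
    placentals = c("human", "chimp", "gorilla", "marmoset", "mouse", "rat",
                   "squirrel", "guinea_pig", "kangaroo_rat", "rabbit",
                   "dog", "cow"))
  # Integrity checks on the shipped data.
  if (sum(meta$selenoprotein_subfamily) != 45L)
    stop("fixture integrity failure: expected 45 selenoprotein subfamilies")
  if (!setequal(colnames(mat), tree$tip.label))
    stop("fixture integrity failure: matrix taxa do not match tree tips")
  if (!setequal(unlist(groups), tree$tip.label))
    stop("fixture integrity failure: group map does not cover the tips")
  structure(list(tree = tree, matrix = mat, meta = meta, groups = groups),
            class = "paper_fixture")
}

#' @export
print.paper_fixture <- function(x, ...) {
  cat("paper_fixture:", nrow(x$matrix), "families x", ncol(x$matrix),
      "taxa;", sum(x$meta$selenoprotein_subfamily), "selenoprotein subfamilies\n")
  invisible(x)
}

#' Fixture census
#'
#' Desk statistics of the packaged presence matrix: total number of
#' selenoprotein subfamilies, the number with Sec presence in the fish and
#' mammalian groups, and the number present in all six groups.
#'
#' @param fixture a `paper_fixture` (default: the packaged one).
#' @return named integer vector with elements `n_subfamilies`, `n_fish`,
#'   `n_mammals`, `n_all_groups`.
#' @export
fixture_census <- function(fixture = load_paper_fixture()) {
  gp <- group_presence(fixture$matrix, fixture$groups)
  mam <- gp[, c("platypus", "marsupials", "placentals"), drop = FALSE]
  c(n_subfamilies = nrow(gp),
    n_fish = sum(gp[, "fish"]),
    n_mammals = sum(apply(mam, 1, any)),
    n_all_groups = sum(apply(gp, 1, all)))
}
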