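fx <- load_paper_fixture()
st <- function(f) unclass(fx$matrix)[f, ]

test_that("birth branches map presence to the most recent common ancestor", {
  expect_equal(infer_birth_branch(fx$tree, st("Fep15")), "Vertebrata")
  expect_equal(infer_birth_branch(fx$tree, st("SPS2b")), "Theria")
  expect_equal(infer_birth_branch(fx$tree, st("TGR")), "Tetrapoda")
  # presence at a single tip puts the birth on that terminal branch
  s <- setNames(rep("absent", length(fx$tree$tip.label)), fx$tree$tip.label)
  s["zebrafish"] <- "sec"
  expect_equal(infer_birth_branch(fx$tree, s), "zebrafish")
  s[] <- "absent"
  expect_error(infer_birth_branch(fx$tree, s), "no observed presence")
})

test_that("Dollo losses are the maximal all-absent branches of the birth clade", {
  expect_equal(dollo_losses(fx$tree, st("SelV"),
                            infer_birth_branch(fx$tree, st("SelV"))),
               "gorilla")
  expect_equal(dollo_losses(fx$tree, st("SelL"), "Vertebrata"), "Tetrapoda")
  expect_equal(dollo_losses(fx$tree, st("SelW1"), "Vertebrata"), "Percomorpha")
  # no absent tips -> no losses; missing-only subtrees emit no loss
  expect_length(dollo_losses(fx$tree, st("GPx1"), "Vertebrata"), 0)
  expect_length(dollo_losses(fx$tree, st("SelU1"), "Vertebrata"), 0)
})

test_that("Sankoff labeling solves textbook cases with the irreversibility rule", {
  tr <- read_newick(textConnection("((A:1,B:1)ab:1,(C:1,D:1)cd:1)r;"))
  allsec <- c(A = "sec", B = "sec", C = "sec", D = "sec")
  sk <- sankoff_states(tr, allsec, birth_branch = "r")
  expect_equal(sk$cost, 0)
  expect_true(all(sk$labels == "sec"))
  mixed <- c(A = "sec", B = "sec", C = "cys", D = "cys")
  sk <- sankoff_states(tr, mixed, birth_branch = "r")
  expect_equal(sk$cost, 1)
  expect_equal(unname(sk$labels[c("r", "ab", "cd")]), c("sec", "sec", "cys"))
})

test_that("GPx6 reconstructs three independent Sec-to-Cys conversions", {
  es <- enumerate_events(fx$tree, fx$matrix, fx$meta)
  conv <- as.data.frame(es)
  conv <- conv[conv$type == "conversion" & conv$family == "GPx6", ]
  expect_setequal(conv$branch, c("marmoset", "Murinae", "rabbit"))
})

test_that("Sankoff cost equals the exhaustive-enumeration minimum", {
  cm <- cost_matrix_default()
  set.seed(401)
  for (rep in 1:12) {
    n <- sample(4:6, 1)
    tr <- random_named_tree(n)
    s <- setNames(sample(c("sec", "cys", "other", "absent", "missing"),
                         n, TRUE, prob = c(.35, .25, .15, .15, .1)),
                  tr$tip.label)
    if (all(s %in% c("absent", "missing"))) s[1] <- "sec"
    birth <- infer_birth_branch(tr, s)
    sk <- sankoff_states(tr, s, cm, birth)
    expect_equal(sk$cost, oracle_sankoff_cost(tr, s, cm, birth))
  }
})

test_that("Dollo loss placement is minimal (brute-force check)", {
  set.seed(402)
  for (rep in 1:10) {
    n <- sample(4:5, 1)
    tr <- random_named_tree(n)
    s <- setNames(sample(c("sec", "absent", "missing"), n, TRUE,
                         prob = c(.5, .35, .15)), tr$tip.label)
    if (all(s %in% c("absent", "missing"))) s[1] <- "sec"
    birth <- infer_birth_branch(tr, s)
    losses <- dollo_losses(tr, s, birth)
    expect_equal(length(losses), oracle_dollo_min_losses(tr, s, birth))
  }
})

test_that("event sets obey the hard invariants", {
  es <- enumerate_events(fx$tree, fx$matrix, fx$meta)
  ev <- as.data.frame(es)
  # exactly one birth per family
  expect_equal(unname(table(ev$family[ev$type == "birth"])),
               rep(1L, nrow(fx$matrix)), ignore_attr = TRUE)
  # no conversion ever restores sec
  expect_false(any(ev$type == "conversion" & ev$to_state == "sec"))
  # losses lie inside the birth clade of their family
  for (i in which(ev$type == "loss")) {
    birth <- ev$branch[ev$type == "birth" & ev$family == ev$family[i]]
    clade <- selevo:::node_names(fx$tree)[
      selevo:::clade_ids(fx$tree, selevo:::node_id(fx$tree, birth))]
    expect_true(ev$branch[i] %in% clade)
  }
})

test_that("event counts are invariant under tip reordering and pass-through nodes", {
  base <- summary(enumerate_events(fx$tree, fx$matrix, fx$meta))
  # permute matrix columns and ladderize the tree
  perm <- fx$matrix[, rev(colnames(fx$matrix))]
  attr(perm, "meta") <- fx$meta
  class(perm) <- class(fx$matrix)
  tr2 <- ape::ladderize(fx$tree)
  expect_equal(summary(enumerate_events(tr2, perm, fx$meta)), base)
  # insert a degree-2 node on the frog terminal branch
  txt <- ape::write.tree(fx$tree)
  txt2 <- sub("frog:1", "(frog:0.5)frogstem:0.5", txt, fixed = TRUE)
  tr3 <- read_newick(textConnection(txt2))
  expect_equal(summary(enumerate_events(tr3, fx$matrix, fx$meta)), base)
})

test_that("ancestral proteomes are consistent with the events along each path", {
  es <- enumerate_events(fx$tree, fx$matrix, fx$meta)
  ev <- as.data.frame(es)
  tr <- fx$tree
  par <- selevo:::tree_parents(tr)
  nn <- selevo:::node_names(tr)
  root <- nn[selevo:::tree_root(tr)]
  walk_set <- function(node) {
    # path of branch (child) names from the root down to `node`
    path <- character()
    i <- selevo:::node_id(tr, node)
    while (!is.na(par[i])) { path <- c(nn[i], path); i <- par[i] }
    fams <- ancestral_selenoproteome(es, root)
    for (br in path) {
      here <- ev[ev$branch == br, , drop = FALSE]
      fams <- union(fams, here$family[here$type == "birth" &
                                        here$to_state == "sec"])
      fams <- setdiff(fams, here$family[here$type %in% c("loss", "conversion")])
    }
    sort(fams)
  }
  internals <- setdiff(tr$node.label, root)
  for (node in internals)
    expect_equal(sort(ancestral_selenoproteome(es, node)), walk_set(node),
                 info = node)
})

test_that("a uniformly-sec family yields one root birth and nothing else", {
  tr <- random_named_tree(5, seed = 7)
  m <- presence_matrix(matrix("sec", 1, 5,
                              dimnames = list("F1", tr$tip.label)))
  es <- enumerate_events(tr, m)
  s <- summary(es)
  expect_equal(unname(s[c("n_births", "n_losses", "n_conversions_total")]),
               c(1L, 0L, 0L))
  expect_equal(as.data.frame(es)$branch[1], "n1")
})
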