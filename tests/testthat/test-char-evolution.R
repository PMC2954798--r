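# brute-force MPR state sets: enumerate all internal assignments, collect the
# states at each node across assignments attaining the minimum
brute_mpr_sets <- function(tree, matrix, i) {
  ntip <- length(tree$tip.label)
  nn <- ntip + tree$Nnode
  cells <- matrix$masks[match(tree$tip.label, matrix$taxa), i]
  allowed <- lapply(cells, function(m) which(bitwAnd(m, bitwShiftL(1L, 0:9)) > 0L) - 1L)
  states <- sort(unique(unlist(allowed)))
  nodesets <- lapply(seq_len(nn), function(v)
    if (v <= ntip) allowed[[v]] else states)
  grid <- expand.grid(nodesets)
  E <- tree$edge
  cost <- apply(grid, 1, function(assign) {
    sum(assign[E[, 1]] != assign[E[, 2]])
  })
  best <- min(cost)
  sel <- grid[cost == best, , drop = FALSE]
  lapply(seq_len(nn), function(v) sort(unique(sel[, v])))
}

test_that("MPR state sets match brute-force enumeration", {
  # spec worked case: 0,0,1,1 on ((A,B),(C,D)) has root set {0,1}
  m <- char_matrix(rbind(A = "0", B = "0", C = "1", D = "1"))
  tr <- parse_newick("((A,B),(C,D));")
  s <- mpr_state_sets(tr, m, 1)
  expect_equal(s[[5]], c(0L, 1L))
  # constant character: every node fixed
  mc <- char_matrix(rbind(A = "1", B = "1", C = "1", D = "1"))
  sc <- mpr_state_sets(tr, mc, 1)
  expect_true(all(vapply(sc, identical, TRUE, y = 1L)))
  # randomized against enumeration (with missing data)
  for (s_ in 1:5) {
    m2 <- random_matrix(5, 4, seed = 950 + s_, bl = 0.6)
    cells <- m2$raw
    cells[sample(length(cells), 3)] <- "?"
    m2 <- char_matrix(cells, taxa = m2$taxa)
    tr2 <- root_on_outgroup(simulate_tree(5, labels = m2$taxa), m2$taxa[1])
    for (i in seq_len(m2$n_characters)) {
      mine <- mpr_state_sets(tr2, m2, i)
      want <- brute_mpr_sets(tr2, m2, i)
      ntip <- 5
      for (v in (ntip + 1):(ntip + tr2$Nnode))
        expect_equal(mine[[v]], as.integer(want[[v]]),
                     label = paste("seed", s_, "char", i, "node", v))
    }
  }
})

test_that("acctran and deltran are MPRs differing in change placement", {
  # classic ambiguous case: 1,0,0,1 on a ladder; one parallelism vs reversal
  m <- char_matrix(rbind(O = "1", A = "0", B = "0", C = "1"))
  tr <- root_on_outgroup(parse_newick("(O,(A,(B,C)));"), "O")
  st <- fitch_length(tr, m)$per_char_steps
  expect_equal(st[1], 2L)
  ac <- acctran(tr, m, 1)
  de <- deltran(tr, m, 1)
  expect_equal(nrow(ac), 2L)
  expect_equal(nrow(de), 2L)
  # ACCTRAN pushes a change onto the earlier (deeper) branch, DELTRAN keeps
  # the ancestral state longer: the deepest changing branch under ACCTRAN is
  # at least as rootward as under DELTRAN
  depth <- function(tree, node) {
    d <- 0
    root <- setdiff(tree$edge[, 1], tree$edge[, 2])[1]
    while (node != root) {
      node <- tree$edge[tree$edge[, 2] == node, 1]
      d <- d + 1
    }
    d
  }
  expect_lte(min(vapply(ac$node, depth, 0, tree = tr)),
             min(vapply(de$node, depth, 0, tree = tr)))
  expect_false(identical(ac$node, de$node))
  # unambiguous single origin: both optimizations place the same change
  m1 <- char_matrix(rbind(O = "0", A = "0", B = "1", C = "1"))
  ac1 <- acctran(tr, m1, 1); de1 <- deltran(tr, m1, 1)
  expect_equal(ac1[, c("node", "from", "to")], de1[, c("node", "from", "to")])
  expect_equal(nrow(ac1), 1L)
})

test_that("optimized change totals always equal the Fitch steps", {
  for (s in 1:10) {
    m <- random_matrix(7, 8, seed = 970 + s, bl = 0.5)
    tr <- root_on_outgroup(ape::unroot(attr(m, "truth")$tree), m$taxa[1])
    st <- fitch_length(tr, m)$per_char_steps
    for (i in seq_len(m$n_characters)) {
      expect_equal(nrow(acctran(tr, m, i)), st[i])
      expect_equal(nrow(deltran(tr, m, i)), st[i])
    }
  }
})

test_that("missing-data leaves never change on their pendant branch", {
  m <- char_matrix(rbind(O = "0", A = "0", B = "?", C = "1", D = "1"))
  tr <- root_on_outgroup(parse_newick("(O,((A,B),(C,D)));"), "O")
  for (ch in list(acctran(tr, m, 1), deltran(tr, m, 1))) {
    leafB <- which(tr$tip.label == "B")
    expect_false(leafB %in% ch$node)
  }
})

test_that("clade synapomorphies are the unambiguous subtending changes", {
  # three clean binary characters define the clade; one ambiguous one doesn't
  cells <- rbind(O = c("0", "0", "0", "0"),
                 A = c("1", "1", "1", "1"),
                 B = c("1", "1", "1", "0"),
                 C = c("0", "0", "0", "1"),
                 D = c("0", "0", "0", "0"))
  m <- char_matrix(cells, taxon_class = c(O = "outgroup"))
  res <- heuristic_search(m, search_config(4, 10, seed = 1, collapse = "none"))
  syn <- clade_synapomorphies(res$mpts, m, c("A", "B"))
  expect_setequal(syn$char, 1:3)
  expect_equal(unique(syn$from), 0L)
  expect_equal(unique(syn$to), 1L)
  expect_equal(syn$label, sprintf("%d:0->1", syn$char))
  expect_true(all(syn$homoplasy_free[syn$char <= 3]))
  expect_error(clade_synapomorphies(res$mpts, m, c("A", "C")), "absent")
})

test_that("homoplasy flags equal the per-character CI = 1 test", {
  m <- random_matrix(6, 10, seed = 987, bl = 0.5)
  tr <- ape::unroot(attr(m, "truth")$tree)
  sb <- fitch_length(tr, m)
  for (i in seq_len(m$n_characters)) {
    expect_equal(homoplasy_free(list(tr), m, i),
                 sb$per_char_steps[i] == sb$per_char_min[i])
  }
})
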