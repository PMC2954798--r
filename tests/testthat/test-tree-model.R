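test_that("newick round-trips and bipartitions are canonical", {
  tr <- parse_newick("((A,B),(C,D));")
  expect_equal(sort(tr$tip.label), c("A", "B", "C", "D"))
  expect_equal(as.character(bipartitions(tr)), "C|D")  # side away from A
  tr2 <- parse_newick(write_newick(tr))
  expect_equal(bipartitions(tr2), bipartitions(tr))
  star <- parse_newick("(A,B,C);")
  expect_length(bipartitions(star), 0)
  expect_error(parse_newick("((A,B);"))
})

test_that("a resolved n-leaf unrooted tree has n-3 nontrivial splits", {
  for (n in 4:8) {
    tr <- ape::unroot(simulate_tree(n))
    expect_length(bipartitions(tr), n - 3)
  }
  # equal split sets iff isomorphic: permuting labels changes the set
  tr <- simulate_tree(6)
  tr2 <- tr
  tr2$tip.label <- rev(tr2$tip.label)
  same <- setequal(bipartitions(tr), bipartitions(tr2))
  iso <- isTRUE(all.equal(ape::unroot(tr), ape::unroot(tr2),
                          use.tip.label = TRUE))
  expect_equal(same, iso)
})

test_that("strict consensus matches ape and collapses conflicting splits", {
  trees <- lapply(1:6, function(i) simulate_tree(8, seed = i))
  sc <- strict_consensus(trees)
  expect_setequal(as.character(bipartitions(sc)),
                  as.character(bipartitions(ape::consensus(trees))))
  expect_setequal(as.character(bipartitions(strict_consensus(trees[1]))),
                  as.character(bipartitions(trees[[1]])))
  # two 5-leaf trees differing in one split: that branch collapses
  a <- parse_newick("((A,B),((C,D),E));")
  b <- parse_newick("((A,B),((C,E),D));")
  expect_equal(as.character(sort(bipartitions(strict_consensus(list(a, b))))),
               sort(intersect(bipartitions(a), bipartitions(b))))
  expect_error(strict_consensus(list(a, parse_newick("((A,B),(C,F));"))),
               "leaf-set mismatch")
})

test_that("majority-rule frequencies equal a direct tally", {
  set.seed(9)
  trees <- lapply(1:20, function(i) simulate_tree(7))
  mc <- majority_rule_consensus(trees)
  freqs <- attr(mc, "frequencies")
  tally <- table(unlist(lapply(trees, bipartitions)))
  for (k in freqs$split)
    expect_equal(freqs$freq[freqs$split == k], unname(tally[k]) / 20)
  expect_setequal(as.character(bipartitions(mc)),
                  names(tally)[tally / 20 > 0.5])
  # identical trees: every branch at 100%
  mc2 <- majority_rule_consensus(list(trees[[1]], trees[[1]]))
  f2 <- attr(mc2, "frequencies")
  expect_true(all(f2$freq == 1))
  # 2-of-3 split included at 0.5
  a <- parse_newick("((A,B),(C,D));"); b <- parse_newick("((A,C),(B,D));")
  m3 <- majority_rule_consensus(list(a, a, b))
  expect_equal(as.character(bipartitions(m3)), "C|D")
})

test_that("strict is contained in majority, which draws from the input trees", {
  set.seed(4)
  trees <- c(lapply(1:3, function(i) simulate_tree(8, seed = 40)),
             lapply(1:2, function(i) simulate_tree(8)))
  s <- bipartitions(strict_consensus(trees))
  m <- bipartitions(majority_rule_consensus(trees))
  expect_true(all(s %in% m))
  all_splits <- unique(unlist(lapply(trees, bipartitions)))
  expect_true(all(m %in% all_splits))
  for (tr in trees) expect_true(all(s %in% bipartitions(tr)))
})

test_that("adams consensus keeps a wandering taxon at its deepest position", {
  # t6 wanders between two positions inside a stable ladder
  a <- parse_newick("(O,(((A,B),(C,D)),W));")
  b <- parse_newick("(O,(((A,W),B),(C,D)));")
  ad <- adams_consensus(list(a, b))
  st <- strict_consensus(list(a, b))
  # strict keeps only the (C,D) clade; Adams also retains the
  # {A,B,C,D,W} grouping with W attached at its deepest common position
  expect_true("C|D" %in% bipartitions(ad))
  expect_gt(length(bipartitions(ad)), length(bipartitions(st)))
  # identity on a single tree
  one <- adams_consensus(list(a, a))
  expect_setequal(as.character(bipartitions(one)), as.character(bipartitions(a)))
})

test_that("outgroup rooting behaves and unrooting restores topology", {
  tr <- ape::unroot(simulate_tree(7, seed = 2))
  rt <- root_on_outgroup(tr, c("t1"))
  expect_true(ape::is.rooted(rt))
  expect_setequal(as.character(bipartitions(ape::unroot(rt))),
                  as.character(bipartitions(tr)))
  expect_error(root_on_outgroup(tr, tr$tip.label), "all leaves")
  expect_error(root_on_outgroup(tr, character(0)), "non-empty")
  # 4-leaf, single outgroup: outgroup sister to the rest
  t4 <- parse_newick("((A,B),(C,D));")
  r4 <- root_on_outgroup(t4, "A")
  expect_true(ape::is.monophyletic(r4, c("B", "C", "D")))
})

test_that("monophyly and backbone constraints are checked correctly", {
  tr <- parse_newick("((A,(B,C)),(D,(E,F)));")
  spec <- constraint_monophyly(c("B", "C"), outgroup = "A")
  expect_true(satisfies_constraint(tr, spec))
  expect_false(satisfies_constraint(tr, constraint_monophyly(c("B", "D"), "A")))
  expect_error(constraint_monophyly(c("A", "B"), "A"), "outgroup")
  # backbone: restriction must display every backbone split
  bb <- parse_newick("((A,B),C,D);")
  cand_good <- parse_newick("(((A,x),B),((C,y),D));")
  cand_bad <- parse_newick("(((A,C),x),(B,(D,y)));")
  expect_true(satisfies_constraint(cand_good, constraint_backbone(bb)))
  expect_false(satisfies_constraint(cand_bad, constraint_backbone(bb)))
  # refinable: candidate more resolved than the backbone is fine
  bb_star <- parse_newick("(A,B,C,D);")
  expect_true(satisfies_constraint(cand_good, constraint_backbone(bb_star)))
  # invariance under rerooting
  rr <- root_on_outgroup(cand_good, "D")
  expect_true(satisfies_constraint(rr, constraint_backbone(bb)))
})
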