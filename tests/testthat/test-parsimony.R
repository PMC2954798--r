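test_that("fitch steps equal brute-force assignment enumeration", {
  for (s in 1:8) {
    m <- random_matrix(6, 6, seed = 100 + s, bl = 0.6, poly = 0.1)
    tr <- attr(m, "truth")$tree
    got <- fitch_length(tr, m)$per_char_steps
    want <- vapply(seq_len(m$n_characters), brute_char_steps, integer(1),
                   tree = tr, matrix = m)
    expect_equal(got, want)
  }
})

test_that("whole-tree length matches an independent implementation", {
  for (s in 1:6) {
    m <- random_matrix(sample(5:9, 1), 20, seed = 200 + s, bl = 0.5)
    tr <- simulate_tree(length(m$taxa), labels = m$taxa)
    expect_equal(fitch_length(tr, m)$total_length, phangorn_length(tr, m))
  }
})

test_that("constant and all-missing characters add nothing", {
  m <- char_matrix(rbind(A = c("0", "?", "1"), B = c("0", "?", "0"),
                         C = c("0", "?", "1"), D = c("0", "?", "0")))
  tr <- parse_newick("((A,B),(C,D));")
  st <- fitch_length(tr, m)$per_char_steps
  expect_equal(st[1], 0L)
  expect_equal(st[2], 0L)
  m2 <- char_matrix(rbind(A = "1", B = "0", C = "1", D = "0"))
  expect_equal(fitch_length(tr, m2)$total_length,
               fitch_length(tr, m)$total_length - st[1] - st[2])
})

test_that("length is invariant under rerooting and leaf permutation", {
  m <- random_matrix(7, 12, seed = 11, bl = 0.5)
  tr <- attr(m, "truth")$tree
  base <- fitch_length(tr, m)$total_length
  for (og in m$taxa[1:3])
    expect_equal(fitch_length(root_on_outgroup(ape::unroot(tr), og), m)$total_length,
                 base)
  expect_equal(fitch_length(ape::rotateConstr(tr, rev(tr$tip.label)), m)$total_length,
               base)
})

test_that("char_min_steps is the minimum over all trees (incl. polymorphism)", {
  # spec-level cases
  m <- char_matrix(rbind(A = "0", B = "1", C = "0", D = "1"))
  expect_equal(char_min_steps(m, 1), 1L)
  m3 <- char_matrix(rbind(A = "0", B = "1", C = "2", D = "1"))
  expect_equal(char_min_steps(m3, 1), 2L)
  # a state occurring only inside a polymorphic cell costs nothing
  mp <- char_matrix(rbind(A = "0", B = "0", C = "01", D = "0"))
  expect_equal(char_min_steps(mp, 1), 0L)
  # randomized check against exhaustive tree enumeration
  for (s in 1:5) {
    m <- random_matrix(6, 5, seed = 300 + s, bl = 0.7, poly = 0.15)
    for (i in seq_len(m$n_characters)) {
      lens <- vapply(all_topologies(m$taxa), brute_char_steps, integer(1),
                     matrix = m, i = i)
      expect_equal(char_min_steps(m, i), min(lens), label = paste(s, i))
    }
  }
})

test_that("char_max_steps matches the exhaustive-tree maximum", {
  m <- char_matrix(rbind(A = "0", B = "0", C = "0", D = "1", E = "1"))
  expect_equal(char_max_steps(m, 1), 2L)
  lens <- vapply(all_topologies(m$taxa), brute_char_steps, integer(1),
                 matrix = m, i = 1)
  expect_equal(char_max_steps(m, 1), max(lens))
  # constant and autapomorphic characters
  mc <- char_matrix(rbind(A = c("0", "0"), B = c("0", "1"),
                          C = c("0", "0"), D = c("0", "0")))
  expect_equal(char_max_steps(mc, 1), 0L)
  expect_equal(char_max_steps(mc, 2), 1L)
  expect_equal(char_min_steps(mc, 2), 1L)  # g = m marks it RI-uninformative
  # randomized (unambiguous cells only)
  for (s in 1:4) {
    m <- random_matrix(6, 4, seed = 400 + s, bl = 0.7)
    for (i in seq_len(m$n_characters)) {
      lens <- vapply(all_topologies(m$taxa), brute_char_steps, integer(1),
                     matrix = m, i = i)
      expect_equal(char_max_steps(m, i), max(lens), label = paste(s, i))
    }
  }
})

test_that("min <= steps <= max on every character and tree, bounds attained", {
  m <- random_matrix(6, 10, seed = 17, bl = 0.6)
  trees <- all_topologies(m$taxa)
  steps <- sapply(trees, function(tr) fitch_length(tr, m)$per_char_steps)
  for (i in seq_len(m$n_characters)) {
    expect_true(all(steps[i, ] >= char_min_steps(m, i)))
    expect_true(all(steps[i, ] <= char_max_steps(m, i)))
    expect_equal(min(steps[i, ]), char_min_steps(m, i))
    expect_equal(max(steps[i, ]), char_max_steps(m, i))
  }
})

test_that("ensemble indices follow the standard formulas", {
  # homoplasy-free data: CI = RI = 1 on the generating tree
  m <- random_matrix(8, 30, seed = 5, bl = 0.05)
  tr <- attr(m, "truth")$tree
  sb <- fitch_length(tr, m)
  if (all(sb$per_char_steps == sb$per_char_min)) {
    expect_equal(sb$CI, 1)
    expect_equal(sb$RI, 1)
  }
  # independent formula evaluation on random breakdowns
  set.seed(8)
  for (k in 1:10) {
    mins <- sample(0:2, 6, replace = TRUE)
    steps <- mins + sample(0:2, 6, replace = TRUE)
    maxs <- pmax(steps + sample(0:2, 6, replace = TRUE), mins)
    if (sum(steps) == 0) next
    e <- ensemble_indices(steps, mins, maxs)
    expect_equal(e$CI, sum(mins) / sum(steps))
    sel <- maxs > mins
    expect_equal(e$RI, (sum(maxs[sel]) - sum(steps[sel])) /
                       (sum(maxs[sel]) - sum(mins[sel])))
    expect_equal(e$RC, e$CI * e$RI)
  }
  expect_error(ensemble_indices(c(0, 0), c(0, 0), c(0, 0)), "constant")
})

test_that("polytomies rescore identically after collapsing resolutions", {
  # scoring a star equals the best resolution when no signal supports any
  m <- char_matrix(rbind(A = "0", B = "1", C = "2", D = "3"))
  star <- parse_newick("(A,B,C,D);")
  expect_equal(fitch_length(star, m)$total_length, 3)
  res <- parse_newick("((A,B),(C,D));")
  expect_equal(fitch_length(res, m)$total_length, 3)
})
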