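test_that("simulated trees are deterministic and uniform over topologies", {
  t1 <- simulate_tree(8, seed = 5)
  t2 <- simulate_tree(8, seed = 5)
  expect_equal(write_newick(t1), write_newick(t2))
  # unrooted binary tree on n leaves: 2n-3 edges
  expect_equal(nrow(ape::unroot(simulate_tree(59, seed = 1))$edge), 2 * 59 - 3)
  # 4 taxa: the 3 topologies appear ~uniformly
  set.seed(10)
  keys <- replicate(600, paste(sort(bipartitions(simulate_tree(4))),
                               collapse = ";"))
  tab <- table(keys)
  expect_equal(length(tab), 3)
  expect_gt(stats::chisq.test(tab)$p.value, 0.001)
})

test_that("rate controls homoplasy and the change log bounds parsimony", {
  set.seed(11)
  tr <- simulate_tree(10, mean_branch_length = 1)
  # zero rate: all characters constant
  tr0 <- tr; tr0$edge.length <- rep(0, nrow(tr$edge))
  m0 <- simulate_matrix(tr0, sim_config(20))
  expect_equal(fitch_length(tr0, m0)$total_length, 0)
  # parsimony never overcounts relative to the true history
  for (s in 1:5) {
    m <- random_matrix(8, 25, seed = 1000 + s, bl = 0.3)
    truth <- attr(m, "truth")
    expect_lte(fitch_length(truth$tree, m)$total_length, nrow(truth$changes))
  }
  # multiple-hit characters increase with rate (monotone trend on average)
  multi <- vapply(c(0.02, 0.3, 1.5), function(r) {
    tt <- simulate_tree(10, seed = 3); tt$edge.length <- tt$edge.length * r / 0.1
    mm <- simulate_matrix(tt, sim_config(40, seed = 7))
    ch <- attr(mm, "truth")$changes
    sum(table(factor(ch$char, levels = 1:40)) > 1)
  }, numeric(1))
  expect_true(multi[1] <= multi[2] && multi[2] <= multi[3])
})

test_that("low-rate matrices let the search recover the generating splits", {
  # equal branch lengths: every internal branch carries expected signal, so
  # recovery should be essentially perfect at low rates
  hits <- 0; total <- 0
  for (s in 1:6) {
    set.seed(1100 + s)
    tr <- simulate_tree(8)
    tr$edge.length <- rep(0.08, nrow(tr$edge))
    m <- simulate_matrix(tr, sim_config(150))
    res <- heuristic_search(m, search_config(2, 5, seed = s))
    cons <- strict_consensus(res$mpts)
    want <- bipartitions(ape::unroot(tr))
    hits <- hits + sum(want %in% bipartitions(cons))
    total <- total + length(want)
    expect_lte(res$best_length, fitch_length(ape::unroot(tr), m)$total_length)
  }
  expect_gte(hits / total, 0.95)
})

test_that("fossilization hits target fractions without altering states", {
  m <- random_matrix(8, 50, seed = 15, bl = 0.2)
  m$partition <- rep(c("cranial", "pelvic"), c(20, 30))
  plan <- data.frame(taxon = m$taxa[c(2, 5)], fraction = c(0.3, 0.8),
                     drop_partitions = c("cranial", ""))
  f <- apply_fossilization(m, plan)
  s <- matrix_summary(f)
  expect_equal(s$taxa$scored[s$taxa$taxon == m$taxa[2]], round(0.3 * 50))
  expect_equal(s$taxa$scored[s$taxa$taxon == m$taxa[5]], round(0.8 * 50))
  expect_equal(unname(f$taxon_class[m$taxa[2]]), "fossil")
  # surviving cells unchanged
  keep <- f$raw[2, ] != "?"
  expect_equal(f$raw[2, keep], m$raw[2, keep])
  # cranial block blanked first
  expect_true(all(f$raw[2, m$partition == "cranial"] == "?"))
  # fraction 1 leaves the taxon intact
  f1 <- apply_fossilization(m, data.frame(taxon = m$taxa[1], fraction = 1),
                            mark_fossil = FALSE)
  expect_equal(f1$raw[1, ], m$raw[1, ])
  # randomized recount
  set.seed(3)
  for (k in 1:10) {
    fr <- runif(1, 0.05, 0.95)
    fk <- apply_fossilization(m, data.frame(taxon = m$taxa[3], fraction = fr))
    got <- matrix_summary(fk)$taxa
    expect_equal(got$scored[got$taxon == m$taxa[3]], round(fr * 50))
  }
})

test_that("the study-shaped preset has the right anatomy", {
  m <- simulate_osteo59(seed = 4)
  expect_equal(length(m$taxa), 59)
  expect_equal(m$n_characters, 464)
  s <- matrix_summary(m)
  pt <- setNames(s$partitions$n, s$partitions$partition)
  expect_equal(pt[["cranial"]], 95)
  expect_equal(pt[["axial"]], 11)
  expect_equal(pt[["pectoral"]], 188)
  expect_equal(pt[["pelvic"]], 169)
  expect_equal(pt[["misc"]], 1)
  expect_equal(sum(m$taxon_class == "fossil"), 8)
  expect_equal(sum(m$taxon_class == "outgroup"), 2)
  tx <- s$taxa
  frac <- setNames(tx$fraction, tx$taxon)
  expect_equal(unname(round(frac["Limnofregata"], 3)), 0.541)
  expect_equal(tx$scored[tx$taxon == "Limnofregata"], 251L)
  # published completeness fractions, one decimal (percent)
  pubs <- c(Phocavis_maritimus = 7.5, Tonsala_hildegardae = 17.2,
            Copepteryx_hexeris = 44.2, Prophaethon_shrubsolei = 20.5,
            Lithoptila_abdounensis = 24.4, Borvocarbo_stoeffelensis = 7.3)
  for (nm in names(pubs))
    expect_equal(round(100 * unname(frac[nm]), 1), unname(pubs[nm]))
  # plotopterids lack cranial material entirely
  for (nm in c("Plotopterum_joaquinensis", "Tonsala_hildegardae"))
    expect_true(all(m$flavor[m$taxa == nm, m$partition == "cranial"] %in%
                    c("missing", "inapplicable")))
})
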