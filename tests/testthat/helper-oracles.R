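# Independent brute-force oracles the implementation is checked against.
# None of these share code with the scoring/search paths they validate.

# minimum changes of one character on one tree, by exhaustive enumeration of
# internal-node state assignments (leaves pick their cheapest allowed state)
brute_char_steps <- function(tree, matrix, i) {
  ntip <- length(tree$tip.label)
  nn <- ntip + tree$Nnode
  cells <- matrix$masks[match(tree$tip.label, matrix$taxa), i]
  allowed <- lapply(cells, function(m) which(bitwAnd(m, bitwShiftL(1L, 0:9)) > 0L) - 1L)
  states <- sort(unique(unlist(allowed)))
  internals <- setdiff(seq_len(nn), seq_len(ntip))
  grid <- expand.grid(rep(list(states), length(internals)))
  E <- tree$edge
  best <- Inf
  for (r in seq_len(nrow(grid))) {
    assign <- integer(nn)
    assign[internals] <- as.integer(grid[r, ])
    cost <- 0
    for (e in seq_len(nrow(E))) {
      p <- E[e, 1]; ch <- E[e, 2]
      if (ch <= ntip) {
        cost <- cost + as.integer(!(assign[p] %in% allowed[[ch]]))
      } else {
        cost <- cost + as.integer(assign[p] != assign[ch])
      }
    }
    if (cost < best) best <- cost
  }
  as.integer(best)
}

# all unrooted binary topologies on the matrix taxa (via phangorn)
all_topologies <- function(taxa) {
  trees <- unclass(phangorn::allTrees(length(taxa), rooted = FALSE))
  lapply(trees, function(tr) { tr$tip.label <- taxa; tr })
}

# independent tree length: phangorn's Fitch implementation
phangorn_length <- function(tree, matrix) {
  raw <- matrix$raw
  raw[nchar(raw) > 1 & raw != "?"] <- "?"  # phangorn has no polymorphism here
  rownames(raw) <- matrix$taxa
  pd <- phangorn::phyDat(raw, type = "USER", levels = as.character(0:9),
                         ambiguity = "?")
  phangorn::fitch(ape::unroot(tree), pd)
}

# exhaustive minimum length over all trees, optionally keeping only trees
# where `clade` is NOT monophyletic when rooted on `outgroup`
oracle_best_length <- function(matrix, clade = NULL, outgroup = NULL,
                               require_absent = FALSE) {
  best <- Inf
  for (tr in all_topologies(matrix$taxa)) {
    if (!is.null(clade)) {
      rt <- ape::root(tr, outgroup = outgroup, resolve.root = TRUE)
      mono <- ape::is.monophyletic(rt, clade)
      if (require_absent && mono) next
      if (!require_absent && !mono) next
    }
    len <- sum(vapply(seq_len(matrix$n_characters), function(i)
      brute_char_steps(tr, matrix, i) * matrix$weights[i], numeric(1)))
    if (len < best) best <- len
  }
  best
}

# a small random matrix with known seed
random_matrix <- function(n_taxa, n_char, seed, bl = 0.4, poly = 0) {
  set.seed(seed)
  tr <- simulate_tree(n_taxa, mean_branch_length = bl)
  simulate_matrix(tr, sim_config(n_char, polymorphism_prob = poly))
}

# helper: set the branch subtending `side` to length 0 so di2multi contracts it
compute_brlen_for_split <- function(tree, side) {
  tree$edge.length <- rep(1, nrow(tree$edge))
  ids <- sort(match(side, tree$tip.label))
  clades <- fitchkit:::node_clades_ids(tree)
  comp <- sort(match(setdiff(tree$tip.label, side), tree$tip.label))
  for (v in names(clades)) {
    if (identical(clades[[v]], ids) || identical(clades[[v]], comp)) {
      e <- which(tree$edge[, 2] == as.integer(v))
      tree$edge.length[e] <- 0
    }
  }
  tree
}
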