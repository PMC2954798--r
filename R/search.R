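#' Search configuration
#'
#' @param n_replicates number of random addition sequence (RAS) replicates.
#' @param maxtrees cap on equally short trees collected per replicate (the
#'   plateau is explored by swapping on every saved tree until closed or the
#'   cap is hit).
#' @param seed integer seed; the whole search is reproducible given the seed.
#' @param constraint optional [constraint_monophyly()], [constraint_backbone()]
#'   or [constraint_not_monophyly()].
#' @param collapse `"min_length_zero"` (collapse branches whose minimum number
#'   of changes over all most-parsimonious reconstructions is zero, applied to
#'   every saved tree before deduplication) or `"none"`.
#' @param keep_all_shortest keep every distinct shortest tree found across
#'   replicates (otherwise only the first).
#' @return A `search_config` list.
#' @export
search_config <- function(n_replicates = 10, maxtrees = 100, seed = NULL,
                          constraint = NULL,
                          collapse = c("min_length_zero", "none"),
                          keep_all_shortest = TRUE) {
  collapse <- match.arg(collapse)
  stopifnot(n_replicates >= 1, maxtrees >= 1)
  structure(list(n_replicates = as.integer(n_replicates),
                 maxtrees = as.integer(maxtrees), seed = seed,
                 constraint = constraint, collapse = collapse,
                 keep_all_shortest = keep_all_shortest),
            class = "search_config")
}

# Prepares the bitmask data a search consumes: matrix masks aligned to
# matrix$taxa (tip i = taxa[i]) plus penalty characters for positive
# constraints.  Converse constraints become a tree filter.
prep_search_data <- function(matrix, constraint = NULL) {
  masks <- matrix$masks
  weights <- matrix$weights
  n_pen <- 0L
  W <- 0
  filter <- NULL
  if (!is.null(constraint)) {
    if (constraint$kind %in% c("monophyly", "backbone")) {
      W <- length(matrix$taxa) * sum(weights) + 1
      pen <- constraint_penalty(constraint, matrix$taxa, W)
      masks <- cbind(masks, pen$masks)
      weights <- c(weights, rep(W, pen$n))
      n_pen <- pen$n
    } else if (constraint$kind == "not_monophyly") {
      labels <- matrix$taxa
      filter <- function(E) {
        tr <- graph_to_phylo(E, length(labels), labels)
        !has_clade(tr, constraint$clade, constraint$outgroup)
      }
    } else stop("unknown constraint kind")
  }
  list(masks = masks, weights = weights, n_pen = n_pen, W = W,
       filter = filter, ntip = length(matrix$taxa), labels = matrix$taxa,
       offset = n_pen * W)
}

# --- edge-list surgery -------------------------------------------------------

# apply a TBR move (bisect edge e of E, reconnect at anchors a and b; anchor 0
# = the stub left at the bisected endpoint).  Anchors are 1-based rows of E.
apply_tbr_move <- function(E, e, a, b) {
  u <- E[e, 1]; v <- E[e, 2]
  orig <- E
  keep <- rep(TRUE, nrow(E)); keep[e] <- FALSE
  junction <- function(node, anchor) {
    if (anchor == 0) return(node)
    # suppress `node` (now degree 2) and reuse its id as the junction
    inc <- which(keep & (E[, 1] == node | E[, 2] == node))
    nb <- setdiff(as.vector(E[inc, ]), node)
    keep[inc] <<- FALSE
    add <<- rbind(add, nb)                    # merged edge
    # split the anchor edge, inserting the junction
    pe <- orig[anchor, ]
    arow <- which(keep & ((E[, 1] == pe[1] & E[, 2] == pe[2]) |
                          (E[, 1] == pe[2] & E[, 2] == pe[1])))
    if (length(arow) == 1) {
      keep[arow] <<- FALSE
    } else {
      # anchor edge already replaced by the merged edge? cannot happen: anchors
      # exclude edges incident to the suppressed node
      stop("internal error: anchor edge not found")
    }
    add <<- rbind(add, c(pe[1], node), c(node, pe[2]))
    node
  }
  add <- matrix(0L, 0, 2)
  j1 <- junction(u, a)
  j2 <- junction(v, b)
  add <- rbind(add, c(j1, j2))
  rbind(E[keep, , drop = FALSE], add)
}

etree_key <- function(E, ntip, labels) {
  topology_key(graph_to_phylo(E, ntip, labels))
}

# --- stepwise addition -------------------------------------------------------

#' Stepwise (greedy) taxon addition
#'
#' Farris-style tree building: taxa are added in the given order, each on the
#' branch minimising total Fitch length; length ties are broken uniformly at
#' random (use `set.seed` for reproducibility).  Positive constraints are
#' honoured by penalty scoring (violating placements cost more than any data
#' signal, so they are taken only when no satisfying placement exists, and the
#' subsequent TBR phase restores satisfiability).
#'
#' @param matrix a [char_matrix] with at least 3 taxa.
#' @param order taxon labels in addition order (default: matrix order).
#' @param constraint optional positive `constraint_spec`.
#' @return An unrooted binary `phylo`.
#' @export
stepwise_addition <- function(matrix, order = matrix$taxa, constraint = NULL) {
  validate_char_matrix(matrix)
  stopifnot(setequal(order, matrix$taxa), length(order) >= 3)
  sd <- prep_search_data(matrix, constraint)
  idx <- match(order, matrix$taxa)
  E <- stepwise_addition_edges(sd, idx)
  graph_to_phylo(E, sd$ntip, sd$labels)
}

stepwise_addition_edges <- function(sd, order_idx) {
  ntip <- sd$ntip
  root_int <- ntip + 1L
  E <- rbind(c(root_int, order_idx[1]), c(root_int, order_idx[2]),
             c(root_int, order_idx[3]))
  next_int <- ntip + 2L
  for (k in seq_along(order_idx)[-(1:3)]) {
    t <- order_idx[k]
    cost <- c_placement_costs(E, ntip, sd$masks, sd$weights,
                              sd$masks[t, ])
    best <- which(cost == min(cost, na.rm = TRUE))
    pick <- if (length(best) == 1) best else best[sample.int(length(best), 1)]
    a <- E[pick, 1]; b <- E[pick, 2]
    E <- rbind(E[-pick, , drop = FALSE],
               c(a, next_int), c(next_int, b), c(next_int, t))
    next_int <- next_int + 1L
  }
  E
}

# --- TBR ---------------------------------------------------------------------

#' TBR neighbourhood of a tree
#'
#' Enumerates every tree bisection-reconnection rearrangement: each branch is
#' cut, the two fragments' branches are paired in all ways and rejoined; the
#' reconnection reproducing the original tree is excluded.  Distinct
#' reconnections can yield topologically identical trees; no deduplication is
#' performed.
#'
#' @param tree an unrooted binary `phylo` with at least 4 leaves.
#' @return A list of `phylo` objects.
#' @export
tbr_neighbors <- function(tree) {
  tree <- ape::unroot(tree)
  ntip <- length(tree$tip.label)
  if (ntip < 4) stop("need at least 4 leaves")
  E <- tree$edge
  out <- list()
  for (e in seq_len(nrow(E))) {
    u <- E[e, 1]; v <- E[e, 2]
    recs <- function(w) {
      comp <- graph_component(E[-e, , drop = FALSE], w)
      if (length(comp) == 1) return(0L)
      inner <- which(seq_len(nrow(E)) != e &
                     E[, 1] %in% comp & E[, 2] %in% comp &
                     E[, 1] != w & E[, 2] != w)
      c(0L, inner)
    }
    for (a in recs(u)) for (b in recs(v)) {
      if (a == 0 && b == 0) next
      out[[length(out) + 1L]] <-
        graph_to_phylo(apply_tbr_move(E, e, a, b), ntip, tree$tip.label)
    }
  }
  out
}

graph_component <- function(E, start) {
  comp <- start
  repeat {
    nb <- unique(c(E[E[, 1] %in% comp, 2], E[E[, 2] %in% comp, 1]))
    new <- setdiff(nb, comp)
    if (!length(new)) return(comp)
    comp <- c(comp, new)
  }
}

# One replicate: hill-climb by TBR accepting strictly shorter trees, then
# collect equal-length trees by swapping on every saved tree (up to maxtrees).
# `filter(E)` (if any) must hold for every accepted tree.
tbr_search_one <- function(E, sd, maxtrees) {
  ntip <- sd$ntip
  len <- c_tree_length(E, ntip, sd$masks, sd$weights)
  filter <- sd$filter
  if (!is.null(filter) && !filter(E)) {
    mv <- c_tbr_moves(E, ntip, sd$masks, sd$weights, Inf)
    mm <- mv$moves[order(mv$moves$len), , drop = FALSE]
    found <- FALSE
    for (r in seq_len(nrow(mm))) {
      E2 <- apply_tbr_move(E, mm$e[r], mm$a[r], mm$b[r])
      if (filter(E2)) { E <- E2; len <- mm$len[r]; found <- TRUE; break }
    }
    if (!found) return(NULL)  # constraint unsatisfiable from this start
  }
  pool <- list(E)
  keys <- etree_key(E, ntip, sd$labels)
  open <- 1L
  while (open <= length(pool) && length(pool) <= maxtrees) {
    cur <- pool[[open]]
    mv <- c_tbr_moves(cur, ntip, sd$masks, sd$weights, len)
    improved <- FALSE
    if (mv$min < len) {
      mm <- mv$moves[order(mv$moves$len), , drop = FALSE]
      for (r in seq_len(nrow(mm))) {
        if (mm$len[r] >= len) break
        E2 <- apply_tbr_move(cur, mm$e[r], mm$a[r], mm$b[r])
        if (is.null(filter) || filter(E2)) {
          pool <- list(E2)
          keys <- etree_key(E2, ntip, sd$labels)
          open <- 1L
          len <- mm$len[r]
          improved <- TRUE
          break
        }
      }
    }
    if (improved) next
    eq <- mv$moves[mv$moves$len == len, , drop = FALSE]
    for (r in seq_len(nrow(eq))) {
      if (length(pool) >= maxtrees) break
      E2 <- apply_tbr_move(cur, eq$e[r], eq$a[r], eq$b[r])
      k2 <- etree_key(E2, ntip, sd$labels)
      if (k2 %in% keys) next
      if (!is.null(filter) && !filter(E2)) next
      pool[[length(pool) + 1L]] <- E2
      keys <- c(keys, k2)
    }
    open <- open + 1L
  }
  list(len = len, pool = pool, keys = keys)
}

#' Heuristic parsimony search
#'
#' Random addition sequence replicates, each refined by TBR branch swapping
#' that accepts strictly shorter trees and then collects equal-length trees by
#' swapping on every saved tree (up to `maxtrees` per replicate).  The global
#' pool keeps all distinct shortest trees; with
#' `collapse = "min_length_zero"`, branches whose minimum number of changes
#' over all most-parsimonious reconstructions is zero are collapsed before
#' deduplication.  Positive constraints are enforced by penalty characters,
#' converse constraints by move rejection; every returned tree satisfies the
#' constraint.
#'
#' @param matrix a [char_matrix].
#' @param config a [search_config()].
#' @return A `search_result`: `best_length`, `mpts` (list of `phylo`),
#'   `n_mpts`, `log` (per-replicate data frame), `score` (a
#'   `score_breakdown` of the best trees) and `status`.
#' @export
heuristic_search <- function(matrix, config = search_config()) {
  validate_char_matrix(matrix)
  if (!is.null(config$seed)) set.seed(config$seed)
  sd <- prep_search_data(matrix, config$constraint)
  ntaxa <- sd$ntip
  best <- Inf
  pool <- list()
  keys <- character(0)
  log <- data.frame(replicate = integer(0), length = numeric(0),
                    n_trees = integer(0))
  for (rep in seq_len(config$n_replicates)) {
    ord <- sample.int(ntaxa)
    E0 <- stepwise_addition_edges(sd, ord)
    res <- tbr_search_one(E0, sd, config$maxtrees)
    if (is.null(res)) next
    log <- rbind(log, data.frame(replicate = rep, length = res$len - sd$offset,
                                 n_trees = length(res$pool)))
    if (res$len < best - 1e-9) {
      best <- res$len
      pool <- res$pool
      keys <- res$keys
    } else if (res$len <= best + 1e-9 && config$keep_all_shortest) {
      for (i in seq_along(res$pool)) {
        if (!res$keys[i] %in% keys) {
          pool[[length(pool) + 1L]] <- res$pool[[i]]
          keys <- c(keys, res$keys[i])
        }
      }
    }
  }
  if (!length(pool))
    return(structure(list(best_length = NA_real_, mpts = list(), n_mpts = 0L,
                          log = log, score = NULL, status = "failed"),
                     class = "search_result"))
  trees <- lapply(pool, graph_to_phylo, ntip = ntaxa, labels = sd$labels)
  status <- "ok"
  if (!is.null(config$constraint)) {
    sat <- vapply(trees, satisfies_constraint, logical(1),
                  spec = config$constraint)
    if (!all(sat)) {
      trees <- trees[sat]
      status <- if (length(trees)) "ok" else "constraint_unsatisfied"
    }
  }
  if (config$collapse == "min_length_zero" && length(trees)) {
    trees <- lapply(trees, collapse_unsupported, matrix = matrix)
    tkeys <- vapply(trees, topology_key, character(1))
    trees <- trees[!duplicated(tkeys)]
  }
  if (!config$keep_all_shortest && length(trees) > 1) trees <- trees[1]
  score <- if (length(trees)) fitch_length(trees[[1]], matrix) else NULL
  structure(list(best_length = best - sd$offset, mpts = trees,
                 n_mpts = length(trees), log = log, score = score,
                 status = status),
            class = "search_result")
}

#' @export
print.search_result <- function(x, ...) {
  cat("parsimony search:", x$status, "\n")
  cat("best length:", x$best_length, "-", x$n_mpts, "shortest tree(s)\n")
  if (!is.null(x$score))
    cat(sprintf("CI %.3f, RI %.3f\n", x$score$CI, x$score$RI))
  invisible(x)
}

#' Collapse unsupported branches
#'
#' Collapses every internal branch whose minimum number of changes over all
#' most-parsimonious reconstructions is zero (the strict reading of
#' zero-length-branch collapsing: a branch is kept only when *every* MPR
#' places at least one change on it).  The criterion is evaluated by edge
#' contraction: the minimum over MPRs is zero exactly when contracting the
#' branch leaves the Fitch length unchanged.  The collapsed (polytomous) tree
#' rescores to the same length.
#'
#' @param tree a `phylo` on the matrix taxa.
#' @param matrix a [char_matrix].
#' @param rule `"min"` collapses when the minimum over MPRs is zero (default);
#'   `"max"` collapses only when every MPR assigns zero changes (branch length
#'   zero under all reconstructions).
#' @return A `phylo`, possibly with polytomies.
#' @export
collapse_unsupported <- function(tree, matrix, rule = c("min", "max")) {
  rule <- match.arg(rule)
  validate_char_matrix(matrix)
  masks <- masks_for_tree(matrix, tree)
  ntip <- length(tree$tip.label)
  E <- tree$edge
  base <- c_fitch(E, ntip, masks, matrix$weights)$total
  repeat {
    internal <- which(E[, 1] > ntip & E[, 2] > ntip)
    hit <- NA
    for (e in internal) {
      if (rule == "min") {
        E2 <- contract_edge(E, e)
        tot <- c_fitch(E2, ntip, masks, matrix$weights)$total
        if (tot <= base + 1e-9) { hit <- e; E <- E2; break }
      } else {
        if (edge_max_changes(tree, matrix, E, e) == 0) {
          hit <- e; E <- contract_edge(E, e); break
        }
      }
    }
    if (is.na(hit)) break
  }
  graph_to_phylo(E, ntip, tree$tip.label)
}

contract_edge <- function(E, e) {
  u <- E[e, 1]; v <- E[e, 2]
  E <- E[-e, , drop = FALSE]
  E[E == v] <- u
  E
}

#' Exhaustive parsimony search
#'
#' Scores every unrooted binary topology (at most 9 taxa) and returns all
#' shortest trees; the independent oracle for the heuristic machinery.
#'
#' @param matrix a [char_matrix] with 4-9 taxa.
#' @param constraint optional `constraint_spec`; only satisfying trees compete.
#' @return A `search_result` (with `n_scored` trees examined in `log`).
#' @export
exhaustive_search <- function(matrix, constraint = NULL) {
  validate_char_matrix(matrix)
  n <- length(matrix$taxa)
  if (n < 4 || n > 9) stop("exhaustive search supports 4-9 taxa")
  masks <- matrix$masks
  w <- matrix$weights
  ntip <- n
  best <- Inf
  winners <- list()
  n_scored <- 0L
  E0 <- rbind(c(ntip + 1L, 1L), c(ntip + 1L, 2L), c(ntip + 1L, 3L))
  recurse <- function(E, k, next_int) {
    if (k > n) {
      n_scored <<- n_scored + 1L
      len <- c_fitch(E, ntip, masks, w)$total
      if (len > best + 1e-9) return()
      tr <- graph_to_phylo(E, ntip, matrix$taxa)
      if (!is.null(constraint) && !satisfies_constraint(tr, constraint)) return()
      if (len < best - 1e-9) { best <<- len; winners <<- list(tr) }
      else winners[[length(winners) + 1L]] <<- tr
      return()
    }
    for (e in seq_len(nrow(E))) {
      p <- E[e, 1]; c_ <- E[e, 2]
      E2 <- rbind(E[-e, , drop = FALSE],
                  c(p, next_int), c(next_int, c_), c(next_int, k))
      recurse(E2, k + 1L, next_int + 1L)
    }
  }
  recurse(E0, 4L, ntip + 2L)
  score <- if (length(winners)) fitch_length(winners[[1]], matrix) else NULL
  structure(list(best_length = best, mpts = winners,
                 n_mpts = length(winners),
                 log = data.frame(replicate = 1L, length = best,
                                  n_trees = length(winners),
                                  n_scored = n_scored),
                 score = score,
                 status = if (length(winners)) "ok" else "constraint_unsatisfied"),
            class = "search_result")
}

# Can any character change on edge e in some MPR?  Exact test by double leaf
# augmentation: a character admits an MPR assigning state a to one endpoint
# and b to the other iff attaching pendant test leaves fixed to a and b leaves
# its step count unchanged.  Used by the optional "max" collapse rule: a
# branch is collapsed only when no MPR of any character places a change on it.
edge_max_changes <- function(tree, matrix, E, e) {
  ntip <- length(tree$tip.label)
  masks <- masks_for_tree(matrix, tree)
  base <- c_fitch(E, ntip, masks, matrix$weights)$steps
  obs <- matrix$masks[matrix$flavor == "observed" | matrix$flavor == "polymorphic"]
  states <- mask_to_states(Reduce(bitwOr, obs, 0L))
  if (length(states) < 2) return(0L)
  u <- E[e, 1]; v <- E[e, 2]
  maxid <- max(E)
  t1 <- maxid + 1L; t2 <- maxid + 2L
  big <- rbind(masks, matrix(1L, t2 - nrow(masks), ncol(masks)))
  for (a in states) for (b in states) {
    if (a == b) next
    big[t1, ] <- bitwShiftL(1L, a)
    big[t2, ] <- bitwShiftL(1L, b)
    E2 <- rbind(E, c(u, t1), c(v, t2))
    st <- c_fitch(E2, ntip, big, matrix$weights)$steps
    if (any(st == base)) return(1L)
  }
  0L
}
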