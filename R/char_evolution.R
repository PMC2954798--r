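# Most-parsimonious reconstructions and character optimization.
#
# MPR state sets are computed exactly by leaf augmentation: state s occurs at
# node v in some most-parsimonious reconstruction of character i if and only
# if attaching a pendant test leaf fixed to s at v leaves the character's step
# count unchanged.  This avoids any reliance on uppass formulas and is
# validated against brute-force enumeration in the test suite.

# per-node MPR state-set bitmasks for all characters: (ntip+Nnode) x nchar
mpr_state_sets_all <- function(tree, matrix) {
  validate_char_matrix(matrix)
  masks <- masks_for_tree(matrix, tree)
  ntip <- length(tree$tip.label)
  nn <- ntip + tree$Nnode
  E <- tree$edge
  w <- rep(1, matrix$n_characters)
  base <- c_fitch(E, ntip, masks, w)$steps
  obs <- matrix$masks[matrix$flavor == "observed" | matrix$flavor == "polymorphic"]
  states <- mask_to_states(Reduce(bitwOr, obs, 0L))
  t1 <- nn + 1L
  big <- rbind(masks, matrix(1L, t1 - nrow(masks), matrix$n_characters))
  sets <- matrix(0L, nn, matrix$n_characters)
  for (v in seq_len(nn)) {
    E2 <- rbind(E, c(v, t1))
    for (s in states) {
      big[t1, ] <- bitwShiftL(1L, s)
      st <- c_fitch(E2, ntip, big, w)$steps
      hit <- st == base
      sets[v, hit] <- bitwOr(sets[v, hit], bitwShiftL(1L, s))
    }
  }
  sets
}

#' MPR state sets of one character
#'
#' For a rooted tree, the set of states each node takes in at least one
#' most-parsimonious reconstruction of character `i`.
#'
#' @param tree a rooted `phylo` on the matrix taxa (polytomies allowed).
#' @param matrix a [char_matrix].
#' @param i 1-based character index.
#' @return A list, indexed by ape node id (tips `1..ntip`, internals
#'   following), of integer state vectors.
#' @export
mpr_state_sets <- function(tree, matrix, i) {
  sets <- mpr_state_sets_all(tree, matrix)
  lapply(seq_len(nrow(sets)), function(v) mask_to_states(sets[v, i]))
}

# Sankoff dynamic programme for one character with unit (Fitch) costs and a
# top-down backtrace; `policy` resolves backtrace ties: ACCTRAN prefers the
# state differing from the parent (changes as early/rootward as possible),
# DELTRAN prefers the parent's state (changes as late as possible).  At leaves
# the parent's state is always preferred when attainable, so missing-data
# leaves never generate changes on pendant branches.  Remaining ties take the
# smallest state.  The backtrace is exact: total changes equal the Fitch steps.
sankoff_changes <- function(tree, matrix, i, policy = c("deltran", "acctran")) {
  policy <- match.arg(policy)
  validate_char_matrix(matrix)
  masks <- masks_for_tree(matrix, tree)
  ntip <- length(tree$tip.label)
  nn <- ntip + tree$Nnode
  cells <- masks[, i]
  space <- mask_to_states(Reduce(bitwOr, cells, 0L))
  ns <- length(space)
  kids <- split(tree$edge[, 2], tree$edge[, 1])
  root <- setdiff(tree$edge[, 1], tree$edge[, 2])[1]
  S <- matrix(Inf, nn, ns)
  post <- rev(preorder_nodes(tree))
  for (v in post) {
    kv <- kids[[as.character(v)]]
    if (is.null(kv)) {
      S[v, ] <- ifelse(bitwAnd(cells[v], bitwShiftL(1L, space)) > 0L, 0, Inf)
    } else {
      tot <- numeric(ns)
      for (ch in kv) {
        m <- min(S[ch, ])
        tot <- tot + pmin(S[ch, ] , m + 1)
      }
      S[v, ] <- tot
      if (v <= ntip)  # a tip used as root keeps its own observation
        S[v, ] <- S[v, ] + ifelse(bitwAnd(cells[v], bitwShiftL(1L, space)) > 0L, 0, Inf)
    }
  }
  chosen <- integer(nn)
  # root-state ties are resolved from the smaller root subtree: under
  # outgroup rooting that is the outgroup side, so the ancestral state is
  # drawn from the outgroup when the data allow it
  rootcand <- which(S[root, ] == min(S[root, ]))
  rkids <- kids[[as.character(root)]]
  if (length(rootcand) > 1 && length(rkids) > 1) {
    sizes <- vapply(rkids, function(ch) length(subtree_tips(tree, ch)),
                    integer(1))
    small <- rkids[which.min(sizes)]
    pref <- rootcand[S[small, rootcand] == min(S[small, rootcand])]
    if (length(pref)) rootcand <- pref
  }
  chosen[root] <- space[rootcand[1]]
  changes <- data.frame(char = integer(0), node = integer(0),
                        parent = integer(0), from = integer(0), to = integer(0))
  for (v in preorder_nodes(tree)) {
    if (v == root) next
    p <- tree$edge[tree$edge[, 2] == v, 1]
    a <- chosen[p]
    ai <- match(a, space)
    costs <- S[v, ] + (space != a)
    cand <- which(costs == min(costs))
    if (policy == "acctran" && v > ntip) {
      # prefer a change when tied (place it as early as possible)
      other <- setdiff(cand, ai)
      pick <- if (length(other)) other[1] else cand[1]
    } else {
      # DELTRAN, and every leaf: keep the parent's state when attainable
      pick <- if (ai %in% cand) ai else cand[1]
    }
    chosen[v] <- space[pick]
    if (chosen[v] != a)
      changes <- rbind(changes, data.frame(char = i, node = v, parent = p,
                                           from = a, to = chosen[v]))
  }
  attr(changes, "states") <- chosen
  changes
}

subtree_tips <- function(tree, node) {
  ntip <- length(tree$tip.label)
  if (node <= ntip) return(node)
  kids <- tree$edge[tree$edge[, 1] == node, 2]
  unlist(lapply(kids, subtree_tips, tree = tree))
}

# preorder node ids (root first)
preorder_nodes <- function(tree) {
  kids <- split(tree$edge[, 2], tree$edge[, 1])
  root <- setdiff(tree$edge[, 1], tree$edge[, 2])[1]
  out <- integer(0)
  stack <- root
  while (length(stack)) {
    v <- stack[length(stack)]
    stack <- stack[-length(stack)]
    out <- c(out, v)
    kv <- kids[[as.character(v)]]
    if (!is.null(kv)) stack <- c(stack, kv)
  }
  out
}

#' ACCTRAN / DELTRAN character optimization
#'
#' One most-parsimonious reconstruction of character `i` on a rooted tree,
#' assigning changes as early (ACCTRAN: ambiguity resolved toward the root,
#' favouring reversals) or as late (DELTRAN: favouring parallelisms) as
#' possible.  The total number of changes always equals the character's Fitch
#' step count.
#'
#' @param tree a rooted `phylo` (root it with [root_on_outgroup()]).
#' @param matrix a [char_matrix].
#' @param i 1-based character index.
#' @return A data frame of changes: `char`, `node` (ape id of the child end of
#'   the branch), `parent`, `from`, `to`; attribute `"states"` holds the full
#'   node-state assignment.
#' @export
acctran <- function(tree, matrix, i) sankoff_changes(tree, matrix, i, "acctran")

#' @rdname acctran
#' @export
deltran <- function(tree, matrix, i) sankoff_changes(tree, matrix, i, "deltran")

#' Unambiguous synapomorphies of a clade
#'
#' The character changes assigned to the branch subtending `clade` identically
#' in *every* most-parsimonious reconstruction of *every* supplied tree: both
#' branch endpoints must have singleton MPR state sets that differ.  Changes
#' are rendered 1-based in the conventional `"index:from->to"` notation.
#'
#' @param mpts list of `phylo` trees (e.g. the MPTs of a search), all
#'   containing the clade; unrooted trees are rooted on the matrix's outgroup
#'   taxa (`taxon_class == "outgroup"`).
#' @param matrix a [char_matrix].
#' @param clade character vector of taxon labels.
#' @return A data frame: `char`, `from`, `to`, `label`, `homoplasy_free`
#'   (per-character CI = 1 on all supplied trees).
#' @export
clade_synapomorphies <- function(mpts, matrix, clade) {
  if (inherits(mpts, "phylo")) mpts <- list(mpts)
  outgroup <- names(matrix$taxon_class)[matrix$taxon_class == "outgroup"]
  per_tree <- lapply(mpts, function(tr) {
    if (!ape::is.rooted(tr)) {
      if (!length(outgroup)) stop("unrooted trees need outgroup taxa in the matrix")
      tr <- root_on_outgroup(tr, outgroup)
    }
    node <- find_clade_node(tr, clade)
    if (is.na(node)) stop("clade absent from a supplied tree")
    p <- tr$edge[tr$edge[, 2] == node, 1]
    sets <- mpr_state_sets_all(tr, matrix)
    list(tr = tr, up = sets[p, ], down = sets[node, ])
  })
  nchar_ <- matrix$n_characters
  singleton <- function(m) bitwAnd(m, m - 1L) == 0L & m > 0L
  bitlog <- function(m) as.integer(round(log2(pmax(m, 1L))))
  first <- per_tree[[1]]
  ok <- singleton(first$up) & singleton(first$down) & first$up != first$down
  from <- bitlog(first$up)
  to <- bitlog(first$down)
  for (pt in per_tree[-1]) {
    cand <- singleton(pt$up) & singleton(pt$down) & pt$up != pt$down
    ok <- ok & cand & bitlog(pt$up) == from & bitlog(pt$down) == to
  }
  idx <- which(ok)
  hfree <- vapply(idx, function(i) homoplasy_free(mpts, matrix, i), logical(1))
  data.frame(char = idx, from = as.integer(from[idx]), to = as.integer(to[idx]),
             label = sprintf("%d:%d->%d", idx, as.integer(from[idx]),
                             as.integer(to[idx])),
             homoplasy_free = hfree, stringsAsFactors = FALSE)
}

find_clade_node <- function(tree, clade) {
  ntip <- length(tree$tip.label)
  clades <- node_clades_ids(tree)
  target <- sort(match(clade, tree$tip.label))
  if (anyNA(target)) return(NA_integer_)
  for (v in names(clades))
    if (identical(sort(clades[[v]]), target)) return(as.integer(v))
  NA_integer_
}

node_clades_ids <- function(tree) {
  ntip <- length(tree$tip.label)
  nn <- ntip + tree$Nnode
  desc <- vector("list", nn)
  for (i in seq_len(ntip)) desc[[i]] <- i
  for (v in rev(preorder_nodes(tree))) {
    kids <- tree$edge[tree$edge[, 1] == v, 2]
    if (length(kids)) desc[[v]] <- sort(unlist(desc[kids]))
  }
  names(desc) <- seq_len(nn)
  desc[(ntip + 1):nn]
}

#' Is a character homoplasy-free on a set of trees?
#'
#' `TRUE` when the character's realized steps equal its minimum conceivable
#' steps on every supplied tree (per-character CI = 1).
#'
#' @param mpts list of `phylo` trees.
#' @param matrix a [char_matrix].
#' @param i 1-based character index.
#' @return Logical.
#' @export
homoplasy_free <- function(mpts, matrix, i) {
  if (inherits(mpts, "phylo")) mpts <- list(mpts)
  m <- char_min_steps(matrix, i)
  for (tr in mpts) {
    masks <- masks_for_tree(matrix, tr)
    st <- c_fitch(tr$edge, length(tr$tip.label), masks, matrix$weights)$steps
    if (st[i] != m) return(FALSE)
  }
  TRUE
}
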