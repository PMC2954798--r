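#' Parse and write newick trees
#'
#' Thin wrappers around `ape::read.tree` / `ape::write.tree` so that all tree
#' text I/O goes through one place.
#'
#' @param text a newick string.
#' @return `parse_newick`: a `phylo`; `write_newick`: a newick string.
#' @export
parse_newick <- function(text) {
  tr <- ape::read.tree(text = text)
  if (is.null(tr)) stop("newick parse error in: ", text)
  tr
}

#' @rdname parse_newick
#' @param tree a `phylo`.
#' @export
write_newick <- function(tree) ape::write.tree(tree)

#' Nontrivial bipartitions of a tree
#'
#' One bipartition per internal branch; trivial (singleton) splits are
#' excluded.  Each split is stored canonically as the side not containing the
#' reference taxon (the alphabetically first leaf label), sorted, so two trees
#' on the same leaf set share a split if and only if the canonical keys match.
#'
#' @param tree a `phylo` (rooted or not).
#' @return A character vector of canonical split keys (taxa joined by `"|"`);
#'   attribute `"sets"` holds the corresponding taxon-label lists.
#' @export
bipartitions <- function(tree) {
  ntip <- length(tree$tip.label)
  ref <- sort(tree$tip.label)[1]
  out <- character(0)
  sets <- list()
  if (ntip >= 4) {
    clades <- node_clades(tree)
    for (cl in clades) {
      if (length(cl) <= 1 || length(cl) >= ntip - 1) next
      side <- if (ref %in% cl) setdiff(tree$tip.label, cl) else cl
      if (length(side) < 2 || length(side) > ntip - 2) next
      key <- paste(sort(side), collapse = "|")
      if (!key %in% out) {
        out <- c(out, key)
        sets[[key]] <- sort(side)
      }
    }
  }
  structure(out, sets = sets[out])
}

# tip-label sets descending from each internal node (excluding the root set)
node_clades <- function(tree) {
  ntip <- length(tree$tip.label)
  kids <- split(tree$edge[, 2], tree$edge[, 1])
  pre <- preorder_nodes(tree)
  desc <- vector("list", max(tree$edge))
  for (i in seq_len(ntip)) desc[[i]] <- tree$tip.label[i]
  for (v in rev(pre)) {
    kv <- kids[[as.character(v)]]
    if (!is.null(kv)) desc[[v]] <- unlist(desc[kv])
  }
  desc[setdiff(unique(tree$edge[, 1]), pre[1])]
}

# canonical topology hash on a fixed leaf set
topology_key <- function(tree) paste(sort(bipartitions(tree)), collapse = ";")

# --- undirected graph <-> phylo ---------------------------------------------

# E: 2-column matrix of undirected node pairs; tips are ids 1..ntip with
# labels[i] the label of tip i.  Internal ids arbitrary (> ntip).
graph_to_phylo <- function(E, ntip, labels) {
  stopifnot(nrow(E) >= 1)
  adj <- split(c(E[, 2], E[, 1]), c(E[, 1], E[, 2]))
  ids <- as.integer(names(adj))
  internals <- ids[ids > ntip]
  # root at an internal node adjacent to tip 1 (deterministic)
  root <- if (length(internals)) {
    cand <- intersect(adj[["1"]], internals)
    if (length(cand)) min(cand) else min(internals)
  } else stop("graph has no internal node")
  # BFS assigning new ids: tips keep 1..ntip, internals renumbered in preorder
  newid <- integer(max(ids))
  newid[seq_len(ntip)] <- seq_len(ntip)
  nexti <- ntip + 1L
  edge <- matrix(0L, nrow(E), 2)
  k <- 0L
  stack <- list(c(root, 0L))
  while (length(stack)) {
    top <- stack[[length(stack)]]
    stack[[length(stack)]] <- NULL
    v <- top[1]; parent <- top[2]
    if (v > ntip) { newid[v] <- nexti; nexti <- nexti + 1L }
    if (parent > 0) {
      k <- k + 1L
      edge[k, ] <- c(newid[parent], newid[v])
    }
    for (nb in rev(adj[[as.character(v)]])) {
      if (nb != parent) stack[[length(stack) + 1L]] <- c(nb, v)
    }
  }
  # DFS preorder appends each edge when its child is first visited, which is
  # exactly ape's cladewise order
  tr <- structure(list(edge = edge, tip.label = labels,
                       Nnode = nexti - ntip - 1L),
                  class = "phylo", order = "cladewise")
  tr
}

phylo_graph_edges <- function(tree) tree$edge

#' Root a tree on an outgroup
#'
#' If the outgroup forms a split of the tree the root is inserted on the
#' branch separating it from the ingroup; otherwise the tree is rooted on the
#' branch leading to the first outgroup taxon.
#'
#' @param tree a `phylo`.
#' @param outgroup character vector of outgroup taxon labels (non-empty,
#'   proper subset of the leaves).
#' @return A rooted `phylo`.
#' @export
root_on_outgroup <- function(tree, outgroup) {
  if (!length(outgroup)) stop("outgroup must be non-empty")
  if (!all(outgroup %in% tree$tip.label)) stop("outgroup taxa not in tree")
  if (length(outgroup) >= length(tree$tip.label))
    stop("outgroup cannot contain all leaves")
  og <- if (length(outgroup) > 1 && ape::is.monophyletic(tree, outgroup))
    outgroup else outgroup[1]
  ape::root(tree, outgroup = og, resolve.root = TRUE)
}

# does the (rooted or unrooted) tree, rooted on `outgroup`, contain `clade`?
has_clade <- function(tree, clade, outgroup) {
  ntip <- length(tree$tip.label)
  clade <- intersect(clade, tree$tip.label)
  if (length(clade) < 2) return(TRUE)
  if (length(clade) == ntip) return(FALSE)
  rest <- setdiff(tree$tip.label, clade)
  if (!all(outgroup %in% rest)) return(FALSE)
  ref <- sort(tree$tip.label)[1]
  side <- if (ref %in% clade) rest else clade
  key <- paste(sort(side), collapse = "|")
  if (length(side) < 2 || length(side) > ntip - 2) {
    # clade of size ntip-1: true iff remaining taxon attaches at the root,
    # i.e. the rest (singleton) side never forms... a clade of all-but-one
    # non-outgroup taxa exists iff the excluded taxon is adjacent to the root
    # after rooting; fall back to ape
    rt <- root_on_outgroup(tree, outgroup)
    return(ape::is.monophyletic(rt, clade))
  }
  key %in% bipartitions(tree)
}
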