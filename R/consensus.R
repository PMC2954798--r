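# Consensus trees are built from canonical split keys (see bipartitions());
# any set of pairwise-compatible splits oriented away from the reference taxon
# forms a laminar family, so a rooted cluster tree (root = all taxa) realises
# exactly those splits.

# build a phylo from a character vector of split keys over `taxa`
tree_from_splits <- function(keys, taxa, freqs = NULL) {
  clusters <- lapply(keys, function(k) strsplit(k, "|", fixed = TRUE)[[1]])
  ntip <- length(taxa)
  ord <- order(vapply(clusters, length, integer(1)), decreasing = TRUE)
  clusters <- clusters[ord]
  if (!is.null(freqs)) freqs <- freqs[ord]
  ncl <- length(clusters)
  # parent of a cluster/tip: smallest strictly containing cluster, else root
  parent_of <- function(set, self) {
    best <- 0L; bestsize <- Inf
    for (i in seq_len(ncl)) {
      if (!is.na(self) && i == self) next
      cl <- clusters[[i]]
      if (length(cl) > length(set) && all(set %in% cl) &&
          length(cl) < bestsize) {
        best <- i; bestsize <- length(cl)
      }
    }
    best
  }
  rootid <- ntip + 1L
  clid <- ntip + 1L + seq_len(ncl)
  edges <- matrix(0L, 0, 2)
  for (i in seq_len(ncl)) {
    p <- parent_of(clusters[[i]], i)
    edges <- rbind(edges, c(if (p == 0) rootid else clid[p], clid[i]))
  }
  for (t in seq_len(ntip)) {
    p <- parent_of(taxa[t], NA)
    edges <- rbind(edges, c(if (p == 0) rootid else clid[p], t))
  }
  tr <- structure(list(edge = edges, tip.label = taxa, Nnode = ncl + 1L),
                  class = "phylo")
  if (!is.null(freqs)) tr$node.label <- c("", sprintf("%g", freqs))
  ape::reorder.phylo(tr, "cladewise")
}

check_same_leaves <- function(trees) {
  labs <- sort(trees[[1]]$tip.label)
  for (t in trees)
    if (!identical(sort(t$tip.label), labs)) stop("leaf-set mismatch between trees")
  labs
}

#' Strict consensus tree
#'
#' Contains exactly the bipartitions present in every input tree.
#'
#' @param trees a list of `phylo` objects on the same leaf set.
#' @return A `phylo`.
#' @export
strict_consensus <- function(trees) {
  if (inherits(trees, "phylo")) trees <- list(trees)
  check_same_leaves(trees)
  common <- bipartitions(trees[[1]])
  for (t in trees[-1]) common <- intersect(common, bipartitions(t))
  tree_from_splits(common, sort(trees[[1]]$tip.label))
}

#' Majority-rule consensus tree
#'
#' Includes the bipartitions whose (weighted) frequency exceeds `threshold`;
#' node labels carry the frequencies as percentages.
#'
#' @param trees a list of `phylo` objects on the same leaf set.
#' @param threshold inclusion threshold as a fraction in `[0.5, 1]`; a split
#'   is kept when its frequency is strictly greater.
#' @param weights optional per-tree weights (default: equal).  With several
#'   trees saved per bootstrap pseudoreplicate, give each replicate total
#'   weight 1 by weighting its trees by `1/n_saved`.
#' @return A `phylo` whose internal node labels are split frequencies in
#'   percent; attribute `"frequencies"` holds a data frame (split, freq).
#' @export
majority_rule_consensus <- function(trees, threshold = 0.5, weights = NULL) {
  if (inherits(trees, "phylo")) trees <- list(trees)
  if (threshold < 0.5 || threshold > 1) stop("threshold must be in [0.5, 1]")
  check_same_leaves(trees)
  if (is.null(weights)) weights <- rep(1, length(trees))
  stopifnot(length(weights) == length(trees))
  tally <- new.env(parent = emptyenv())
  for (i in seq_along(trees)) {
    for (key in bipartitions(trees[[i]])) {
      prev <- if (is.null(tally[[key]])) 0 else tally[[key]]
      tally[[key]] <- prev + weights[i]
    }
  }
  keys <- ls(tally)
  freq <- vapply(keys, function(k) tally[[k]], numeric(1)) / sum(weights)
  keep <- freq > threshold
  tr <- tree_from_splits(keys[keep], sort(trees[[1]]$tip.label),
                         freqs = round(100 * freq[keep], 2))
  attr(tr, "frequencies") <- data.frame(split = keys, freq = unname(freq),
                                        stringsAsFactors = FALSE)
  tr
}

#' Adams consensus tree
#'
#' The classical Adams (1972) consensus of rooted trees: recursively, the leaf
#' set is divided by the product (common refinement) of the root partitions of
#' all input trees, each class is solved recursively on the restricted trees.
#' A taxon whose placement "wanders" between input trees is attached at its
#' deepest common position instead of collapsing the whole region, which is
#' why Adams consensus can be more informative than strict consensus.
#'
#' @param trees a list of rooted `phylo` objects on the same leaf set, or
#'   unrooted trees together with `outgroup`.
#' @param outgroup optional outgroup labels used to root the trees first.
#' @return A rooted `phylo`.
#' @export
adams_consensus <- function(trees, outgroup = NULL) {
  if (inherits(trees, "phylo")) trees <- list(trees)
  check_same_leaves(trees)
  if (!is.null(outgroup))
    trees <- lapply(trees, root_on_outgroup, outgroup = outgroup)
  else if (!all(vapply(trees, ape::is.rooted, logical(1))))
    stop("trees must be rooted (or supply `outgroup`)")
  nested <- lapply(trees, phylo_to_nested)
  res <- adams_rec(nested)
  parse_newick(paste0(nested_to_newick(res), ";"))
}

# phylo -> nested list of leaf labels
phylo_to_nested <- function(tree) {
  ntip <- length(tree$tip.label)
  kids <- split(tree$edge[, 2], tree$edge[, 1])
  root <- setdiff(tree$edge[, 1], tree$edge[, 2])[1]
  build <- function(v) {
    if (v <= ntip) return(tree$tip.label[v])
    lapply(kids[[as.character(v)]], build)
  }
  collapse_unary(build(root))
}

collapse_unary <- function(x) {
  if (!is.list(x)) return(x)
  x <- lapply(x, collapse_unary)
  if (length(x) == 1) return(x[[1]])
  x
}

nested_leaves <- function(x) if (!is.list(x)) x else unlist(lapply(x, nested_leaves))

# restrict a nested tree to a leaf subset, collapsing empty/unary nodes
nested_restrict <- function(x, keep) {
  if (!is.list(x)) return(if (x %in% keep) x else NULL)
  kids <- Filter(Negate(is.null), lapply(x, nested_restrict, keep = keep))
  if (!length(kids)) return(NULL)
  if (length(kids) == 1) return(kids[[1]])
  kids
}

adams_rec <- function(nested) {
  leaves <- sort(nested_leaves(nested[[1]]))
  if (length(leaves) == 1) return(leaves)
  # block membership of each leaf in each tree's root partition
  sig <- vapply(nested, function(tr) {
    if (!is.list(tr)) return(setNames("1", tr)[leaves])
    blocks <- lapply(tr, nested_leaves)
    member <- character(length(leaves))
    names(member) <- leaves
    for (b in seq_along(blocks)) member[blocks[[b]]] <- as.character(b)
    member
  }, character(length(leaves)))
  classes <- split(leaves, apply(sig, 1, paste, collapse = "."))
  if (length(classes) == 1)
    stop("degenerate root partition in Adams consensus")  # cannot happen
  kids <- lapply(classes, function(cl) {
    if (length(cl) == 1) return(cl)
    adams_rec(lapply(nested, nested_restrict, keep = cl))
  })
  names(kids) <- NULL
  kids
}

nested_to_newick <- function(x) {
  if (!is.list(x)) return(x)
  paste0("(", paste(vapply(x, nested_to_newick, character(1)), collapse = ","), ")")
}
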