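#' Topological constraints for tree searches
#'
#' Three kinds of constraint are supported:
#' * `constraint_monophyly()`: a taxon set must form a clade on the tree
#'   rooted by the outgroup;
#' * `constraint_backbone()`: pruning a candidate tree to the backbone's taxa
#'   must yield a topology refinable to the backbone (the restriction may be
#'   more resolved but must not conflict); `free_taxa` (and any taxa absent
#'   from the backbone) may attach anywhere;
#' * `constraint_not_monophyly()`: the converse constraint used for Bremer
#'   decay — the taxon set must NOT form a clade.
#'
#' @param clade character vector of taxon labels required (or forbidden) to be
#'   monophyletic; must not intersect the outgroup.
#' @param outgroup outgroup taxon labels used to root trees for the clade test.
#' @return A `constraint_spec` object.
#' @export
constraint_monophyly <- function(clade, outgroup) {
  if (length(intersect(clade, outgroup)))
    stop("constrained clade must not contain outgroup taxa")
  structure(list(kind = "monophyly", clade = clade, outgroup = outgroup),
            class = "constraint_spec")
}

#' @rdname constraint_monophyly
#' @param backbone a `phylo` on a subset of the matrix taxa.
#' @param free_taxa taxa allowed to attach anywhere (e.g. fossils); taxa not
#'   in the backbone are free implicitly.
#' @export
constraint_backbone <- function(backbone, free_taxa = character()) {
  structure(list(kind = "backbone", backbone = backbone,
                 free_taxa = free_taxa), class = "constraint_spec")
}

#' @rdname constraint_monophyly
#' @export
constraint_not_monophyly <- function(clade, outgroup) {
  structure(list(kind = "not_monophyly", clade = clade, outgroup = outgroup),
            class = "constraint_spec")
}

#' Does a tree satisfy a constraint?
#'
#' Monophyly is evaluated on the tree rooted by the constraint's outgroup;
#' backbone compatibility is root-invariant (split containment).
#'
#' @param tree a `phylo` whose leaves include the constrained taxa.
#' @param spec a `constraint_spec`.
#' @return `TRUE` or `FALSE`.
#' @export
satisfies_constraint <- function(tree, spec) {
  stopifnot(inherits(spec, "constraint_spec"))
  switch(spec$kind,
    monophyly = has_clade(tree, spec$clade, spec$outgroup),
    not_monophyly = !has_clade(tree, spec$clade, spec$outgroup),
    backbone = displays_backbone(tree, spec$backbone),
    stop("unknown constraint kind: ", spec$kind)
  )
}

displays_backbone <- function(tree, backbone) {
  bb_taxa <- backbone$tip.label
  if (!all(bb_taxa %in% tree$tip.label)) stop("backbone taxa missing from tree")
  splits <- backbone_splits(backbone)
  if (!length(splits)) return(TRUE)
  cand <- attr(bipartitions(tree), "sets")
  all_taxa <- tree$tip.label
  for (sp in splits) {
    ok <- FALSE
    for (side in cand) {
      comp <- setdiff(all_taxa, side)
      if ((all(sp$X %in% side) && all(sp$Y %in% comp)) ||
          (all(sp$X %in% comp) && all(sp$Y %in% side))) { ok <- TRUE; break }
    }
    if (!ok) return(FALSE)
  }
  TRUE
}

# nontrivial splits of the backbone as taxon-label pairs
backbone_splits <- function(backbone) {
  keys <- bipartitions(backbone)
  sets <- attr(keys, "sets")
  lapply(sets, function(s) list(X = s, Y = setdiff(backbone$tip.label, s)))
}

# Encode positive constraints as high-weight binary penalty characters: one
# character per required split, scoring exactly 1 extra step when (and only
# when) the tree displays the split.  Appending these to the data lets the
# unconstrained search machinery handle constrained searches; the constant
# k * W is subtracted from reported lengths.
constraint_penalty <- function(spec, taxa, weight) {
  if (spec$kind == "monophyly") {
    m <- matrix(1L, length(taxa), 1)
    m[taxa %in% spec$clade, 1] <- 2L
    list(masks = m, n = 1L, weight = weight)
  } else if (spec$kind == "backbone") {
    splits <- backbone_splits(spec$backbone)
    free <- union(spec$free_taxa, setdiff(taxa, spec$backbone$tip.label))
    m <- matrix(FULL_MASK, length(taxa), length(splits))
    for (j in seq_along(splits)) {
      m[taxa %in% setdiff(splits[[j]]$X, free), j] <- 1L
      m[taxa %in% setdiff(splits[[j]]$Y, free), j] <- 2L
    }
    list(masks = m, n = length(splits), weight = weight)
  } else {
    NULL  # converse constraints are handled by move rejection, not penalties
  }
}
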