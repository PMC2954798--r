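#' Fitch parsimony score of a tree
#'
#' Computes per-character Fitch steps (unordered states, equal or supplied
#' weights) together with the per-character step bounds and the ensemble fit
#' indices.  Polytomies are scored with the state-count generalisation of the
#' Fitch rule (a node with k children whose most widely shared state occurs in
#' K child sets adds k - K steps), so collapsed trees rescore exactly.
#' Missing and inapplicable cells carry the full state set; polymorphic cells
#' are satisfiable by any member state at zero cost.
#'
#' @param tree a `phylo` whose leaves equal the matrix taxa.
#' @param matrix a [char_matrix].
#' @param informative_only restrict all sums to parsimony-informative
#'   characters (PAUP*-style alternative convention for the ensemble indices).
#' @return A `score_breakdown`: list with `total_length`, `per_char_steps`,
#'   `per_char_min`, `per_char_max`, `per_char_ci`, `CI`, `RI`, `RC`.
#' @export
fitch_length <- function(tree, matrix, informative_only = FALSE) {
  validate_char_matrix(matrix)
  if (!setequal(tree$tip.label, matrix$taxa))
    stop("tree leaves and matrix taxa differ")
  masks <- masks_for_tree(matrix, tree)
  res <- c_fitch(tree$edge, length(tree$tip.label), masks, matrix$weights)
  steps <- as.integer(res$steps)
  mins <- vapply(seq_len(matrix$n_characters), function(i)
    char_min_steps(matrix, i), integer(1))
  maxs <- vapply(seq_len(matrix$n_characters), function(i)
    char_max_steps(matrix, i), integer(1))
  idx <- seq_len(matrix$n_characters)
  if (informative_only) idx <- informative_characters(matrix)
  ens <- if (sum(steps[idx]) == 0) list(CI = NA_real_, RI = NA_real_,
                                        RC = NA_real_)
         else ensemble_indices(steps[idx], mins[idx], maxs[idx],
                               matrix$weights[idx])
  structure(list(
    total_length = res$total,
    per_char_steps = steps,
    per_char_min = mins,
    per_char_max = maxs,
    per_char_ci = ifelse(steps > 0, mins / steps, NA_real_),
    CI = ens$CI, RI = ens$RI, RC = ens$RC
  ), class = "score_breakdown")
}

#' @export
print.score_breakdown <- function(x, ...) {
  cat(sprintf("tree length %g, CI %.3f, RI %.3f, RC %.3f\n",
              x$total_length, x$CI, x$RI, x$RC))
  invisible(x)
}

#' Minimum conceivable steps of one character
#'
#' The minimum number of steps the character can take on *any* tree.  For
#' unordered characters this is (size of a minimum hitting set of the cell
#' state sets) - 1: each cell must be satisfied by some chosen state
#' (polymorphic cells by any member; missing/inapplicable cells by every
#' state) and grouping equal choices costs one step per additional state.
#'
#' @param matrix a [char_matrix].
#' @param i 1-based character index.
#' @return Non-negative integer.
#' @export
char_min_steps <- function(matrix, i) {
  cells <- matrix$masks[, i]
  cells <- cells[cells != FULL_MASK]
  if (!length(cells)) return(0L)
  u <- Reduce(bitwOr, cells)
  bits <- bitwShiftL(1L, mask_to_states(u))
  for (k in seq_along(bits)) {
    combos <- combn(bits, k)
    for (jj in seq_len(ncol(combos))) {
      S <- sum(combos[, jj])
      if (all(bitwAnd(cells, S) > 0L)) return(k - 1L)
    }
  }
  length(bits) - 1L
}

#' Maximum conceivable steps of one character
#'
#' For an unordered character the maximum over trees equals the number of
#' unambiguously scored taxa minus the largest single-state frequency among
#' them; ambiguous (polymorphic) and missing cells contribute nothing.
#'
#' @param matrix a [char_matrix].
#' @param i 1-based character index.
#' @return Non-negative integer.
#' @export
char_max_steps <- function(matrix, i) {
  obs <- matrix$masks[matrix$flavor[, i] == "observed", i]
  if (!length(obs)) return(0L)
  as.integer(length(obs) - max(table(obs)))
}

#' Ensemble consistency and retention indices
#'
#' `CI = sum(m) / sum(s)`, `RI = (sum(g) - sum(s)) / (sum(g) - sum(m))`,
#' `RC = CI * RI`, with characters where `g = m` (no retention information)
#' excluded from the RI sums.  Weighted sums when weights differ from 1.
#'
#' @param steps,mins,maxs integer vectors of realized, minimum and maximum
#'   steps per character.
#' @param weights per-character weights.
#' @return List with `CI`, `RI`, `RC`.
#' @export
ensemble_indices <- function(steps, mins, maxs, weights = rep(1, length(steps))) {
  S <- sum(weights * steps)
  M <- sum(weights * mins)
  if (S == 0) stop("all characters constant: CI undefined")
  CI <- M / S
  ri_idx <- maxs > mins
  G2 <- sum(weights[ri_idx] * maxs[ri_idx])
  S2 <- sum(weights[ri_idx] * steps[ri_idx])
  M2 <- sum(weights[ri_idx] * mins[ri_idx])
  RI <- if (any(ri_idx)) (G2 - S2) / (G2 - M2) else NA_real_
  list(CI = CI, RI = RI, RC = CI * RI)
}
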