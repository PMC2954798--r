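#' Nonparametric bootstrap clade support
#'
#' Each pseudoreplicate resamples the characters with replacement (implemented
#' as integer resampling weights, so the bitmask data are shared), runs a
#' capped heuristic search, and contributes its saved shortest trees'
#' bipartition frequencies with total weight 1 (each tree weighted by
#' 1/n_saved).  The summary reports, per clade, the percentage of
#' pseudoreplicates supporting it.
#'
#' @param matrix a [char_matrix].
#' @param base_config a [search_config()] used for each pseudoreplicate search
#'   (the classic defaults are 10 addition replicates and maxtrees 100).
#' @param n_pseudoreplicates number of bootstrap pseudoreplicates.
#' @param seed integer seed.
#' @return A `support_summary` data frame: `split` (canonical key), `taxa`
#'   (collapsed label list), `bootstrap_pct`; attribute `"n_pseudoreplicates"`.
#' @export
bootstrap_support <- function(matrix, base_config = search_config(n_replicates = 10),
                              n_pseudoreplicates = 100, seed = NULL) {
  validate_char_matrix(matrix)
  if (!is.null(seed)) set.seed(seed)
  m <- matrix$n_characters
  tally <- new.env(parent = emptyenv())
  for (b in seq_len(n_pseudoreplicates)) {
    wts <- tabulate(sample.int(m, m, replace = TRUE), m) * matrix$weights
    # zero-weight characters contribute nothing; drop them for speed
    keep <- wts > 0
    bmat <- subset_character_idx(matrix, which(keep))
    bmat$weights <- wts[keep]
    cfg <- base_config
    cfg$seed <- NULL  # one RNG stream for the whole bootstrap
    res <- heuristic_search(bmat, cfg)
    if (!length(res$mpts)) next
    wtree <- 1 / length(res$mpts)
    for (tr in res$mpts) {
      for (key in bipartitions(tr)) {
        prev <- if (is.null(tally[[key]])) 0 else tally[[key]]
        tally[[key]] <- prev + wtree
      }
    }
  }
  keys <- ls(tally)
  pct <- 100 * vapply(keys, function(k) tally[[k]], numeric(1)) / n_pseudoreplicates
  out <- data.frame(split = keys, taxa = vapply(strsplit(keys, "|", fixed = TRUE),
                                                paste, character(1), collapse = ","),
                    bootstrap_pct = unname(pct), stringsAsFactors = FALSE)
  out <- out[order(-out$bootstrap_pct), ]
  rownames(out) <- NULL
  attr(out, "n_pseudoreplicates") <- n_pseudoreplicates
  class(out) <- c("support_summary", "data.frame")
  out
}

#' Bremer decay values
#'
#' For each supplied clade, searches for the shortest tree in which the clade
#' is *not* monophyletic (a converse-constraint search) and reports the length
#' difference from the unconstrained optimum.  Under-searching can only
#' overestimate decay, never underestimate it.
#'
#' @param matrix a [char_matrix].
#' @param clades list of taxon-label vectors (e.g. the clades of the strict
#'   consensus), or a `phylo` whose internal clades are used.
#' @param base_config a [search_config()] for the converse searches.
#' @param best_length the unconstrained optimum; computed by a search with
#'   `base_config` when missing.
#' @param outgroup outgroup labels for the clade test; defaults to the
#'   matrix's `taxon_class == "outgroup"` taxa.
#' @return A data frame: `clade` (collapsed labels), `decay`,
#'   `converse_length`.
#' @export
bremer_support <- function(matrix, clades, base_config = search_config(),
                           best_length = NULL, outgroup = NULL) {
  validate_char_matrix(matrix)
  if (is.null(outgroup))
    outgroup <- names(matrix$taxon_class)[matrix$taxon_class == "outgroup"]
  if (!length(outgroup)) stop("no outgroup taxa available for the clade test")
  if (inherits(clades, "phylo")) {
    sets <- attr(bipartitions(clades), "sets")
    og_side <- function(s) if (any(outgroup %in% s)) setdiff(clades$tip.label, s) else s
    clades <- lapply(sets, og_side)
    clades <- clades[!vapply(clades, function(s) any(outgroup %in% s), logical(1))]
  }
  if (is.null(best_length))
    best_length <- heuristic_search(matrix, base_config)$best_length
  rows <- lapply(clades, function(cl) {
    cfg <- base_config
    cfg$constraint <- constraint_not_monophyly(cl, outgroup)
    res <- heuristic_search(matrix, cfg)
    conv <- res$best_length
    data.frame(clade = paste(sort(cl), collapse = ","),
               decay = conv - best_length, converse_length = conv,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
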