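#' Morphological character matrix
#'
#' Container for a taxa x characters matrix of discrete unordered characters.
#' Every cell is a *state set*: a subset of the digit states 0-9 together with
#' a flavor saying how the cell was coded.  Observed cells hold exactly one
#' state, polymorphic cells two or more; missing ("?") and inapplicable ("-")
#' cells carry the full state set and are scored identically (they differ only
#' for reporting).
#'
#' Internally cells are bitmasks (bit `s` = state `s`), the representation the
#' scoring kernels consume.
#'
#' @param cells character matrix (taxa x characters) of cell codings: a digit,
#'   several digits for a polymorphism, `"?"` for missing or `"-"` for
#'   inapplicable.  Row names, if present, are used as taxon labels.
#' @param taxa character vector of taxon labels.
#' @param partition character vector, one partition label per character.
#'   Defaults to `"all"`.
#' @param weights numeric vector of positive per-character weights (default 1).
#' @param taxon_class named character vector classifying taxa as `"extant"`,
#'   `"fossil"` or `"outgroup"`; unlisted taxa are `"extant"`.
#' @return An object of class `"char_matrix"`: a list with elements `taxa`,
#'   `masks` (integer bitmask matrix), `flavor` (character matrix), `raw`
#'   (the cell codings), `n_characters`, `partition`, `weights`, `ordering`
#'   (all `"unordered"`) and `taxon_class`.
#' @examples
#' m <- char_matrix(rbind(A = c("0", "1"), B = c("1", "?")))
#' m$n_characters
#' @export
char_matrix <- function(cells, taxa = rownames(cells), partition = NULL,
                        weights = NULL, taxon_class = NULL) {
  cells <- as.matrix(cells)
  if (is.null(taxa)) stop("taxon labels required (rownames or `taxa`)")
  taxa <- as.character(taxa)
  if (anyDuplicated(taxa)) stop("duplicate taxon label: ",
                                taxa[duplicated(taxa)][1])
  if (length(taxa) != nrow(cells)) stop("taxa/cells dimension mismatch")
  nch <- ncol(cells)
  if (is.null(partition)) partition <- rep("all", nch)
  if (length(partition) != nch) stop("one partition label per character required")
  if (is.null(weights)) weights <- rep(1, nch)
  if (length(weights) != nch || any(weights <= 0))
    stop("weights must be positive, one per character")

  parsed <- parse_cells(cells)
  cls <- rep("extant", length(taxa))
  names(cls) <- taxa
  if (!is.null(taxon_class)) {
    bad <- setdiff(names(taxon_class), taxa)
    if (length(bad)) stop("taxon_class names unknown: ", bad[1])
    cls[names(taxon_class)] <- taxon_class
  }
  obj <- structure(list(
    taxa = taxa,
    masks = parsed$masks,
    flavor = parsed$flavor,
    raw = unname(cells),
    n_characters = nch,
    partition = as.character(partition),
    weights = as.numeric(weights),
    ordering = rep("unordered", nch),
    taxon_class = cls
  ), class = "char_matrix")
  validate_char_matrix(obj)
  obj
}

# full state set used for missing / inapplicable cells
FULL_MASK <- 1023L

parse_cells <- function(cells) {
  n <- nrow(cells); m <- ncol(cells)
  masks <- matrix(0L, n, m)
  flavor <- matrix("observed", n, m)
  for (j in seq_len(m)) {
    for (i in seq_len(n)) {
      cell <- cells[i, j]
      if (cell == "?") {
        masks[i, j] <- FULL_MASK
        flavor[i, j] <- "missing"
      } else if (cell %in% c("-", "−")) {
        masks[i, j] <- FULL_MASK
        flavor[i, j] <- "inapplicable"
      } else {
        st <- strsplit(cell, "")[[1]]
        if (!all(st %in% as.character(0:9)))
          stop("invalid cell coding '", cell, "' (states must be digits 0-9)")
        st <- unique(as.integer(st))
        masks[i, j] <- sum(bitwShiftL(1L, st))
        flavor[i, j] <- if (length(st) > 1) "polymorphic" else "observed"
      }
    }
  }
  list(masks = masks, flavor = flavor)
}

validate_char_matrix <- function(x) {
  stopifnot(inherits(x, "char_matrix"))
  if (ncol(x$masks) != x$n_characters || nrow(x$masks) != length(x$taxa))
    stop("cell count mismatch")
  if (length(x$partition) != x$n_characters)
    stop("every character needs exactly one partition label")
  if (any(x$masks <= 0L)) stop("empty state set in a cell")
  invisible(x)
}

#' @export
print.char_matrix <- function(x, ...) {
  cat("char_matrix:", length(x$taxa), "taxa x", x$n_characters, "characters\n")
  pt <- table(x$partition)
  cat("partitions:", paste(names(pt), pt, sep = "=", collapse = ", "), "\n")
  tc <- table(x$taxon_class)
  cat("taxa:", paste(names(tc), tc, sep = "=", collapse = ", "), "\n")
  invisible(x)
}

#' @export
`==.char_matrix` <- function(e1, e2) {
  identical(e1$taxa, e2$taxa) && identical(e1$raw, e2$raw) &&
    identical(e1$partition, e2$partition) &&
    identical(e1$weights, e2$weights) &&
    identical(e1$taxon_class, e2$taxon_class)
}

# bitmask rows aligned with a tree's tip numbering
masks_for_tree <- function(mat, tree) {
  idx <- match(tree$tip.label, mat$taxa)
  if (anyNA(idx)) stop("tree tips not all present in matrix: ",
                       tree$tip.label[which(is.na(idx))[1]])
  mat$masks[idx, , drop = FALSE]
}

mask_to_states <- function(mask) which(bitwAnd(mask, bitwShiftL(1L, 0:9)) > 0L) - 1L

#' Summarize a character matrix
#'
#' Per-taxon scored-character counts (observed or polymorphic cells; missing
#' and inapplicable cells count as unscored), per-partition character counts
#' and the number of parsimony-informative characters.
#'
#' @param matrix a [char_matrix].
#' @return A list of class `"matrix_summary"` with `n_taxa`, `n_characters`,
#'   `taxa` (data frame: taxon, class, scored, fraction), `partitions`
#'   (data frame: partition, n) and `n_informative`.
#' @export
matrix_summary <- function(matrix) {
  validate_char_matrix(matrix)
  scored <- rowSums(matrix$flavor == "observed" | matrix$flavor == "polymorphic")
  tx <- data.frame(
    taxon = matrix$taxa,
    class = unname(matrix$taxon_class[matrix$taxa]),
    scored = as.integer(scored),
    fraction = scored / matrix$n_characters,
    stringsAsFactors = FALSE
  )
  pt <- table(matrix$partition)
  structure(list(
    n_taxa = length(matrix$taxa),
    n_characters = matrix$n_characters,
    taxa = tx,
    partitions = data.frame(partition = names(pt), n = as.integer(pt),
                            stringsAsFactors = FALSE),
    n_informative = length(informative_characters(matrix))
  ), class = "matrix_summary")
}

#' @export
print.matrix_summary <- function(x, ...) {
  cat("matrix:", x$n_taxa, "taxa x", x$n_characters, "characters;",
      x$n_informative, "parsimony-informative\n")
  cat("partitions:",
      paste(x$partitions$partition, x$partitions$n, sep = "=", collapse = ", "),
      "\n")
  print(x$taxa, row.names = FALSE)
  invisible(x)
}

#' Keep a subset of taxa
#'
#' The character set is left untouched (no re-filtering of now-constant
#' characters); taxon order is preserved.
#'
#' @param matrix a [char_matrix].
#' @param keep character vector of taxon labels to retain (at least 2).
#' @return A [char_matrix] restricted to `keep`.
#' @export
subset_taxa <- function(matrix, keep) {
  validate_char_matrix(matrix)
  bad <- setdiff(keep, matrix$taxa)
  if (length(bad)) stop("unknown taxon: ", bad[1])
  if (length(keep) < 2) stop("need at least 2 taxa")
  sel <- matrix$taxa %in% keep
  char_matrix(matrix$raw[sel, , drop = FALSE], taxa = matrix$taxa[sel],
              partition = matrix$partition, weights = matrix$weights,
              taxon_class = matrix$taxon_class[matrix$taxa[sel]])
}

#' Keep the characters of one partition
#'
#' @param matrix a [char_matrix].
#' @param partition a partition label present in `matrix$partition`.
#' @return A [char_matrix] with exactly the characters of that partition.
#' @export
subset_characters <- function(matrix, partition) {
  validate_char_matrix(matrix)
  if (!partition %in% matrix$partition) stop("unknown partition label: ", partition)
  sel <- matrix$partition == partition
  subset_character_idx(matrix, which(sel))
}

# internal: keep characters by index (used by ILD resampling too)
subset_character_idx <- function(matrix, idx) {
  char_matrix(matrix$raw[, idx, drop = FALSE], taxa = matrix$taxa,
              partition = matrix$partition[idx], weights = matrix$weights[idx],
              taxon_class = matrix$taxon_class)
}

#' Parsimony-informative characters
#'
#' A character is parsimony-informative when at least two of its states each
#' occur unambiguously (as observed single-state cells) in at least two taxa.
#'
#' @param matrix a [char_matrix].
#' @return Integer vector of 1-based character indices.
#' @export
informative_characters <- function(matrix) {
  validate_char_matrix(matrix)
  out <- integer(0)
  for (j in seq_len(matrix$n_characters)) {
    obs <- matrix$masks[matrix$flavor[, j] == "observed", j]
    if (!length(obs)) next
    counts <- table(obs)
    if (sum(counts >= 2) >= 2) out <- c(out, j)
  }
  out
}
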