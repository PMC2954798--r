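#' Per-character step differences between two trees
#'
#' `d_i = s_i(t_alt) - s_i(t_opt)`: positive values are characters favouring
#' the first (optimal) tree.  The weighted sum of differences equals the
#' whole-tree length difference.
#'
#' @param matrix a [char_matrix].
#' @param t_opt,t_alt `phylo` trees on the matrix taxa.
#' @return Integer vector of length `n_characters`.
#' @export
per_site_diffs <- function(matrix, t_opt, t_alt) {
  validate_char_matrix(matrix)
  s <- function(tr) c_fitch(tr$edge, length(tr$tip.label),
                            masks_for_tree(matrix, tr), matrix$weights)$steps
  as.integer(s(t_alt) - s(t_opt))
}

#' Winning-sites test
#'
#' Exact two-tailed binomial sign test with success probability 1/2 on the
#' counts of characters favouring each tree (zero differences dropped).
#'
#' @param diffs integer vector of per-character step differences
#'   (see [per_site_diffs()]).
#' @return Two-tailed p-value in (0, 1].
#' @export
winning_sites_test <- function(diffs) {
  nz <- diffs[diffs != 0]
  if (!length(nz)) return(1)
  k <- sum(nz > 0)
  min(1, stats::binom.test(k, length(nz), p = 0.5)$p.value)
}

#' Templeton test (Wilcoxon signed-ranks on step differences)
#'
#' Zero differences are dropped and ties receive midranks.  With at most
#' `exact_max` nonzero differences the two-tailed p-value is computed exactly
#' by enumerating all sign assignments of the (tied) ranks; otherwise the
#' normal approximation with tie-corrected variance and a continuity
#' correction is used.
#'
#' @param diffs integer vector of per-character step differences.
#' @param exact_max maximum number of nonzero differences for the exact
#'   enumeration path.
#' @return Two-tailed p-value in (0, 1].
#' @export
templeton_test <- function(diffs, exact_max = 12) {
  nz <- diffs[diffs != 0]
  n <- length(nz)
  if (!n) return(1)
  r <- rank(abs(nz))
  Wpos <- sum(r[nz > 0])
  EW <- sum(r) / 2
  if (n <= exact_max) {
    # enumerate all 2^n sign assignments of the midranks
    dev <- abs(Wpos - EW)
    signs <- as.matrix(expand.grid(rep(list(c(0, 1)), n)))
    W <- as.vector(signs %*% r)
    p <- mean(abs(W - EW) >= dev - 1e-9)
    return(min(1, p))
  }
  tie_term <- sum(vapply(split(r, r), function(g) {
    t <- length(g); t^3 - t
  }, numeric(1)))
  VW <- n * (n + 1) * (2 * n + 1) / 24 - tie_term / 48
  z <- (abs(Wpos - EW) - 0.5) / sqrt(VW)
  min(1, 2 * stats::pnorm(-z))
}

#' Kishino-Hasegawa test (parsimony form)
#'
#' Two-tailed paired t-type test of mean step difference zero over all
#' characters (zeros included), df = n - 1.  The halved p-value is reported
#' alongside: by the Goldman-Anderson-Rodrigo bound the p-value of an SH test
#' is at least p/2, so `half_p > 0.05` means an SH test could not reject the
#' alternative topology either; when `half_p < 0.025` the SH conclusion is
#' unknowable from this test alone.
#'
#' @param diffs integer vector of per-character step differences (length >= 2);
#'   pass a pre-filtered vector to restrict the site universe (e.g. to
#'   informative characters).
#' @return List with `t`, `df`, `p`, `half_p`.
#' @export
kh_test <- function(diffs) {
  n <- length(diffs)
  if (n < 2) stop("need at least 2 characters")
  m <- mean(diffs)
  v <- stats::var(diffs)
  if (v == 0) {
    p <- if (m == 0) 1 else .Machine$double.xmin
    return(list(t = if (m == 0) 0 else Inf, df = n - 1, p = p, half_p = p / 2))
  }
  tstat <- m / sqrt(v / n)
  p <- min(1, 2 * stats::pt(-abs(tstat), df = n - 1))
  list(t = tstat, df = n - 1, p = p, half_p = p / 2)
}

#' Paired-sites comparison of tree sets
#'
#' Evaluates every (optimal, alternative) tree pair and reports, per
#' alternative set, the best-fitting row: the maximal p-value of each test
#' over the pairs (the conservative convention when the alternative is a set
#' of constrained MPTs) together with the extra steps of the alternative's
#' best tree.
#'
#' @param matrix a [char_matrix].
#' @param t_opt a `phylo` or list of optimal trees.
#' @param t_alt a `phylo`, list of alternative trees, or *named list of lists*
#'   (one row per alternative set).
#' @return A `paired_test_result` data frame with columns `alternative`,
#'   `extra_steps`, `winning_sites_p`, `templeton_p`, `kh_p`, `kh_half_p`.
#' @export
compare_topologies <- function(matrix, t_opt, t_alt) {
  if (inherits(t_opt, "phylo")) t_opt <- list(t_opt)
  if (inherits(t_alt, "phylo")) t_alt <- list(t_alt)
  if (inherits(t_alt[[1]], "phylo")) t_alt <- list(alternative = t_alt)
  if (is.null(names(t_alt))) names(t_alt) <- paste0("alt", seq_along(t_alt))
  len <- function(tr) c_fitch(tr$edge, length(tr$tip.label),
                              masks_for_tree(matrix, tr), matrix$weights)$total
  opt_lens <- vapply(t_opt, len, numeric(1))
  rows <- lapply(names(t_alt), function(nm) {
    alts <- t_alt[[nm]]
    if (inherits(alts, "phylo")) alts <- list(alts)
    best <- list(ws = 0, tp = 0, kh = 0, extra = Inf)
    for (ta in alts) for (k in seq_along(t_opt)) {
      d <- per_site_diffs(matrix, t_opt[[k]], ta)
      ws <- winning_sites_test(d)
      tp <- templeton_test(d)
      kh <- kh_test(d)$p
      best$ws <- max(best$ws, ws)
      best$tp <- max(best$tp, tp)
      best$kh <- max(best$kh, kh)
      best$extra <- min(best$extra, sum(matrix$weights * d))
    }
    data.frame(alternative = nm, extra_steps = best$extra,
               winning_sites_p = best$ws, templeton_p = best$tp,
               kh_p = best$kh, kh_half_p = best$kh / 2,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  class(out) <- c("paired_test_result", "data.frame")
  out
}
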