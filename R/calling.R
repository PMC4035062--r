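#' Differential tag enrichment at candidate loci
#'
#' For each candidate locus, counts H3K4me1 tags in a +/- `flank` bp window
#' around the midpoint in both cell types, normalizes to tags per 1e7,
#' computes `log2((norm_a + 1) / (norm_b + 1))`, and tests the two raw
#' counts for a difference in rates with the exact two-sample Poisson test
#' (library sizes as exposures; the conditional binomial form of
#' [stats::poisson.test()]). P-values are Benjamini-Hochberg adjusted and
#' candidates are flagged significant at FDR <= `fdr_cutoff`
#' (default 0.001, i.e. a 0.10 percent false discovery rate).
#'
#' @param track_a,track_b [tag_track()] objects for the two cell types.
#' @param loci Candidate interval tibble (e.g. merged H3K4me1 peaks).
#' @param flank Half-window in bp around locus midpoints.
#' @param fdr_cutoff FDR gate for the `significant` flag.
#' @return Tibble: the locus columns plus `tags_a`, `tags_b`, `norm_a`,
#'   `norm_b`, `log2_fc`, `p_diff`, `fdr`, `significant`.
#' @export
differential_loci <- function(track_a, track_b, loci, flank = 500,
                              fdr_cutoff = 0.001) {
  stopifnot(inherits(track_a, "tag_track"), inherits(track_b, "tag_track"))
  if (track_a$library_size <= 0 || track_b$library_size <= 0) {
    stop("zero library size")
  }
  tags_a <- count_tags(track_a, loci, flank)
  tags_b <- count_tags(track_b, loci, flank)
  norm_a <- normalize_counts(tags_a, track_a$library_size)
  norm_b <- normalize_counts(tags_b, track_b$library_size)
  p <- vapply(seq_along(tags_a), function(i) {
    if (tags_a[i] + tags_b[i] == 0L) return(1)
    stats::poisson.test(c(tags_a[i], tags_b[i]),
                        c(track_a$library_size,
                          track_b$library_size))$p.value
  }, 1)
  fdr <- stats::p.adjust(p, method = "BH")
  out <- tibble::as_tibble(loci)
  out$tags_a <- tags_a
  out$tags_b <- tags_b
  out$norm_a <- norm_a
  out$norm_b <- norm_b
  out$log2_fc <- log2((norm_a + 1) / (norm_b + 1))
  out$p_diff <- p
  out$fdr <- fdr
  out$significant <- fdr <= fdr_cutoff
  out
}

#' Select the top-N cell-type-specific enhancer loci
#'
#' Among candidates passing the FDR gate with fold-change favouring the
#' requested cell type, selects the `n` with the largest absolute
#' fold-change (default 2,000 per cell type). Ties are broken by larger
#' normalized count in the favoured cell, then by coordinate order, so the
#' selection is fully deterministic. The A- and B-specific sets are disjoint
#' by construction (opposite fold-change signs).
#'
#' @param candidates Output of [differential_loci()].
#' @param n Number of loci to select.
#' @param direction `"a"` for loci enriched in cell type A (log2_fc > 0),
#'   `"b"` for cell type B.
#' @return Tibble of the selected candidates with attribute `label`
#'   (`"A-specific"` / `"B-specific"`). Warns and returns all eligible loci
#'   if fewer than `n` pass the gate.
#' @export
select_top_specific <- function(candidates, n = 2000,
                                direction = c("a", "b")) {
  direction <- match.arg(direction)
  if (n <= 0) stop("n must be positive")
  eligible <- candidates$significant &
    if (direction == "a") candidates$log2_fc > 0 else candidates$log2_fc < 0
  x <- candidates[eligible, ]
  fc <- if (direction == "a") x$log2_fc else -x$log2_fc
  fav <- if (direction == "a") x$norm_a else x$norm_b
  ord <- order(-fc, -fav, x$chrom, x$start)
  x <- x[ord, ]
  if (nrow(x) < n) {
    warning("only ", nrow(x), " loci pass the gate (requested ", n, ")")
  } else {
    x <- x[seq_len(n), ]
  }
  attr(x, "label") <- if (direction == "a") "A-specific" else "B-specific"
  x
}

#' Select shared enhancer loci
#'
#' Among candidates whose normalized tag density exceeds `min_norm` in both
#' cell types, selects the `n` loci with the smallest absolute log2
#' fold-change, i.e. the most similar density in the two cell types
#' (default 2,000). Used as a null comparison set for the expression-window
#' analyses.
#'
#' @param candidates Output of [differential_loci()].
#' @param n Number of loci to select.
#' @param min_norm Background gate: both `norm_a` and `norm_b` must exceed
#'   this (tags per 1e7 per window).
#' @return Tibble of selected candidates with attribute `label = "shared"`.
#'   Warns and returns all eligible loci if fewer than `n` qualify.
#' @export
select_shared <- function(candidates, n = 2000, min_norm = 50) {
  if (n <= 0) stop("n must be positive")
  x <- candidates[candidates$norm_a > min_norm & candidates$norm_b > min_norm, ]
  ord <- order(abs(x$log2_fc), -pmin(x$norm_a, x$norm_b), x$chrom, x$start)
  x <- x[ord, ]
  if (nrow(x) < n) {
    warning("only ", nrow(x), " loci above background (requested ", n, ")")
  } else {
    x <- x[seq_len(n), ]
  }
  attr(x, "label") <- "shared"
  x
}
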