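#' Categorize genes by differential expression
#'
#' Three-way partition at the adjusted-p 0.05 gate (strict inequality):
#' `over_A` when `adj_p < alpha` and `log_fc > 0`, `over_B` when
#' `adj_p < alpha` and `log_fc < 0`, otherwise `unchanged`.
#'
#' @param expression Tibble with one row per gene and columns `gene_id`,
#'   `log_fc` (A minus B), `adj_p`.
#' @param alpha Adjusted-p cutoff.
#' @return Named character vector, gene_id -> category.
#' @export
categorize_genes <- function(expression, alpha = 0.05) {
  if (anyDuplicated(expression$gene_id)) {
    stop("duplicate gene_id in expression table")
  }
  sig <- expression$adj_p < alpha
  cat <- ifelse(sig & expression$log_fc > 0, "over_A",
                ifelse(sig & expression$log_fc < 0, "over_B", "unchanged"))
  stats::setNames(cat, expression$gene_id)
}

#' Top differentially expressed genes in one direction
#'
#' Ranks significant genes (adjusted p < `alpha`) of the given direction by
#' descending absolute log fold-change (ties by gene_id) and returns the
#' first `n` — by default the top 300, roughly the top decile of a
#' few-thousand-gene differential set.
#'
#' @param expression Expression tibble (see [categorize_genes()]).
#' @param n Number of genes to return.
#' @param direction `"a"` (overexpressed in A) or `"b"`.
#' @param alpha Significance gate.
#' @return Character vector of gene ids. Warns and returns all eligible
#'   genes if fewer than `n` qualify.
#' @export
top_differential <- function(expression, n = 300, direction = c("a", "b"),
                             alpha = 0.05) {
  direction <- match.arg(direction)
  sel <- expression$adj_p < alpha &
    (if (direction == "a") expression$log_fc > 0 else expression$log_fc < 0)
  x <- expression[sel, ]
  x <- x[order(-abs(x$log_fc), x$gene_id), ]
  if (nrow(x) < n) {
    warning("only ", nrow(x), " eligible genes (requested ", n, ")")
    return(x$gene_id)
  }
  x$gene_id[seq_len(n)]
}

#' Define the expression universe for random controls
#'
#' Union of genes overexpressed in either cell type and genes expressed in
#' both conditions, with no duplicates — the pool from which random control
#' gene sets are drawn (e.g. a 3,174 + 2,670 + 1,058 = 6,902-gene
#' universe).
#'
#' @param expression Expression tibble with an `expressed_both` logical
#'   column (significantly expressed in both conditions).
#' @param alpha Significance gate for the differential categories.
#' @return Character vector of gene ids.
#' @export
define_universe <- function(expression, alpha = 0.05) {
  cat <- categorize_genes(expression, alpha)
  both <- if (!is.null(expression$expressed_both)) {
    expression$gene_id[expression$expressed_both]
  } else character(0)
  unique(c(names(cat)[cat != "unchanged"], both))
}

#' Genes with a TSS within a window of any locus
#'
#' Distance is `|TSS - locus midpoint|`; a gene is included when its minimal
#' distance is strictly below `window`, and appears once with that minimal
#' distance regardless of how many loci are nearby.
#'
#' @param loci Interval tibble.
#' @param genes A [gene_models()] object.
#' @param window Window half-width in bp (> 0).
#' @return Tibble with columns `gene_id`, `min_dist`.
#' @export
genes_within_window <- function(loci, genes, window = 100e3) {
  stopifnot(inherits(genes, "gene_models"))
  if (window <= 0) stop("window must be positive")
  g <- genes$genes
  d <- .nearest_distance(g$chrom, g$tss, loci$chrom, interval_midpoint(loci))
  sel <- d < window
  tibble::tibble(gene_id = g$gene_id[sel], min_dist = d[sel])
}

#' Category composition of genes near loci across window sizes
#'
#' For each window in an ascending ladder (default the eight sizes 20 kb to
#' 2 Mb), counts in-window genes by expression category, reports fractions
#' and the over_A / over_B ratio, and (optionally) a chi-square test of the
#' in-window over_A/over_B split against a comparison gene set.
#'
#' @param loci Interval tibble (e.g. one cell type's specific enhancers).
#' @param genes A [gene_models()] object.
#' @param expression Expression tibble.
#' @param windows Ascending numeric vector of window half-widths in bp.
#' @param comparison Optional character vector of comparison gene ids (e.g.
#'   random controls); when supplied, each window's over_A/over_B counts are
#'   tested against the comparison set's by [chi_square_2x2()].
#' @return Tibble with one row per window: `window`, `n_genes`, `over_a`,
#'   `over_b`, `unchanged`, `frac_over_a`, `frac_over_b`, `frac_unchanged`,
#'   `ratio_a_b`, `chisq`, `p_value`, `empty`.
#' @export
window_scan <- function(loci, genes, expression,
                        windows = c(20e3, 50e3, 100e3, 250e3, 500e3,
                                    750e3, 1e6, 2e6),
                        comparison = NULL) {
  if (is.unsorted(windows, strictly = TRUE)) {
    stop("windows must be strictly ascending")
  }
  cat <- categorize_genes(expression)
  g <- genes$genes
  d <- .nearest_distance(g$chrom, g$tss, loci$chrom, interval_midpoint(loci))
  d <- stats::setNames(d, g$gene_id)
  comp_a <- comp_b <- NA_integer_
  if (!is.null(comparison)) {
    comp_cat <- cat[intersect(comparison, names(cat))]
    comp_a <- sum(comp_cat == "over_A")
    comp_b <- sum(comp_cat == "over_B")
  }
  rows <- lapply(windows, function(w) {
    ids <- names(d)[d < w]
    cc <- cat[ids]
    n <- length(ids)
    oa <- sum(cc == "over_A"); ob <- sum(cc == "over_B")
    un <- sum(cc == "unchanged")
    chisq <- p <- NA_real_
    if (!is.null(comparison) && n > 0L && (oa + ob) > 0L &&
        (comp_a + comp_b) > 0L && (oa + comp_a) > 0L && (ob + comp_b) > 0L) {
      ct <- chi_square_2x2(oa, ob, comp_a, comp_b)
      chisq <- ct$statistic; p <- ct$p_value
    }
    tibble::tibble(
      window = w, n_genes = n, over_a = oa, over_b = ob, unchanged = un,
      frac_over_a = if (n > 0) oa / n else NA_real_,
      frac_over_b = if (n > 0) ob / n else NA_real_,
      frac_unchanged = if (n > 0) un / n else NA_real_,
      ratio_a_b = if (ob > 0) oa / ob else NA_real_,
      chisq = chisq, p_value = p, empty = n == 0L
    )
  })
  do.call(rbind, rows)
}

#' Category composition of genes in distance rings around loci
#'
#' Assigns each gene to the single ring containing its minimal TSS-to-locus
#' distance (`boundaries[i] <= d < boundaries[i+1]`) and reports per-ring
#' category counts and fractions. A single ring `[0, w)` reproduces the
#' [window_scan()] row at window `w`.
#'
#' @param loci Interval tibble.
#' @param genes A [gene_models()] object.
#' @param expression Expression tibble.
#' @param boundaries Ascending ring boundaries in bp, starting at the inner
#'   edge (use 0 for a closed innermost ring).
#' @return Tibble with one row per ring: `ring_low`, `ring_high`,
#'   `n_genes`, `over_a`, `over_b`, `unchanged`, fractions, `empty`.
#' @export
interval_scan <- function(loci, genes, expression,
                          boundaries = c(0, 20e3, 50e3, 100e3, 250e3,
                                         500e3, 750e3, 1e6, 2e6)) {
  if (is.unsorted(boundaries, strictly = TRUE)) {
    stop("ring boundaries must be strictly ascending")
  }
  cat <- categorize_genes(expression)
  g <- genes$genes
  d <- .nearest_distance(g$chrom, g$tss, loci$chrom, interval_midpoint(loci))
  ring <- findInterval(d, boundaries, left.open = FALSE)
  ring[d >= boundaries[length(boundaries)]] <- NA_integer_
  rows <- lapply(seq_len(length(boundaries) - 1L), function(i) {
    ids <- g$gene_id[!is.na(ring) & ring == i]
    cc <- cat[ids]
    n <- length(ids)
    oa <- sum(cc == "over_A"); ob <- sum(cc == "over_B")
    tibble::tibble(
      ring_low = boundaries[i], ring_high = boundaries[i + 1L],
      n_genes = n, over_a = oa, over_b = ob,
      unchanged = sum(cc == "unchanged"),
      frac_over_a = if (n > 0) oa / n else NA_real_,
      frac_over_b = if (n > 0) ob / n else NA_real_,
      empty = n == 0L
    )
  })
  do.call(rbind, rows)
}

#' Enrichment ratio of an observed count over a control count
#'
#' @param count_top Observed count (e.g. top-300 genes near enhancers).
#' @param count_control Control count (> 0).
#' @return `count_top / count_control` rounded to one decimal, as reported
#'   in enrichment statements such as "twice as many ... (109 vs 54)".
#' @export
enrichment_ratio <- function(count_top, count_control) {
  if (count_control <= 0) stop("control count must be positive")
  round(count_top / count_control, 1)
}

#' Direct-simulation null for enhancer-adjacent gene counts
#'
#' Under the null of independence between differential expression and
#' enhancer adjacency, draws `k` random gene sets of size `n` (without
#' replacement) from the universe and counts, per replicate, how many carry
#' an enhancer within the window (the `flags`). Returns the empirical
#' distribution with a 95 percent interval: linear-interpolation (type 7)
#' 2.5th/97.5th percentiles rounded outward to integers.
#'
#' @param universe_flags Named logical vector over the gene universe: does
#'   this gene have an enhancer within the window?
#' @param n Genes sampled per replicate.
#' @param k Number of replicates.
#' @param seed Integer seed.
#' @return List of class `null_distribution`: `k`, `n`, `counts`
#'   (length-k integer vector), `ci_low`, `ci_high`.
#' @export
direct_simulation_ci <- function(universe_flags, n = 300, k = 100000,
                                 seed = 1L) {
  flags <- as.logical(universe_flags)
  N <- length(flags)
  if (n > N) stop("n (", n, ") exceeds universe size (", N, ")")
  set.seed(seed)
  counts <- vapply(seq_len(k), function(i) {
    sum(flags[sample.int(N, n)])
  }, integer(1))
  q <- stats::quantile(counts, c(0.025, 0.975), type = 7, names = FALSE)
  structure(list(k = k, n = n, counts = counts,
                 ci_low = as.integer(floor(q[1])),
                 ci_high = as.integer(ceiling(q[2]))),
            class = "null_distribution")
}

#' @export
print.null_distribution <- function(x, ...) {
  cat("direct-simulation null: k =", x$k, ", n =", x$n,
      ", 95% CI [", x$ci_low, ",", x$ci_high, "]\n")
  invisible(x)
}

#' Sample random control genes from the universe
#'
#' @param universe Character vector of gene ids.
#' @param n Sample size.
#' @param seed Integer seed.
#' @param exclude Optional gene ids to remove from the universe first.
#' @return Character vector of `n` gene ids (uniform, without replacement).
#' @export
sample_controls <- function(universe, n = 300, seed = 1L, exclude = NULL) {
  pool <- setdiff(universe, exclude)
  if (length(pool) < n) {
    stop("universe too small after exclusion: ", length(pool), " < ", n)
  }
  set.seed(seed)
  sample(pool, n)
}
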