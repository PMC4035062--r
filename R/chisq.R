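#' Pearson chi-square test on a 2x2 contingency table
#'
#' The workhorse statistic for between-group enrichment throughout the
#' pipeline (motif counts between enhancer sets, gene-category counts between
#' windows and controls, ontology-term counts between target-gene sets).
#' Pearson's statistic without continuity correction,
#' `N (ad - bc)^2 / ((a+b)(c+d)(a+c)(b+d))`, referred to chi-square with
#' 1 degree of freedom.
#'
#' @param a,b Row 1: group A with / without the feature.
#' @param c,d Row 2: group B with / without the feature.
#' @return A list with elements `statistic`, `df` (= 1) and `p_value`.
#' @examples
#' chi_square_2x2(398, 606, 650, 397)  # p ~ 2.9e-24
#' @export
chi_square_2x2 <- function(a, b, c, d) {
  counts <- c(a = a, b = b, c = c, d = d)
  if (any(is.na(counts)) || any(counts < 0)) {
    stop("all four counts must be non-negative")
  }
  n <- a + b + c + d
  if (n <= 0) stop("degenerate table: total count is zero")
  marg <- c("row1 (a+b)" = a + b, "row2 (c+d)" = c + d,
            "col1 (a+c)" = a + c, "col2 (b+d)" = b + d)
  if (any(marg == 0)) {
    stop("degenerate table: zero marginal ", names(marg)[marg == 0][1])
  }
  stat <- n * (a * d - b * c)^2 / prod(marg)
  list(statistic = stat, df = 1L,
       p_value = stats::pchisq(stat, df = 1L, lower.tail = FALSE))
}
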