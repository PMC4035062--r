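make_expr <- function(gene_id, log_fc, adj_p, expressed_both = TRUE) {
  tibble::tibble(gene_id = gene_id, mean_a = 2^pmax(log_fc, 0),
                 mean_b = 2^pmax(-log_fc, 0), log_fc = log_fc,
                 adj_p = adj_p, expressed_both = expressed_both)
}

test_that("genes are categorized at the strict adjusted-p 0.05 gate", {
  expr <- make_expr(c("g1", "g2", "g3", "g4"),
                    log_fc = c(1, -2, 1, 0.5),
                    adj_p = c(0.04, 0.001, 0.5, 0.05))
  cat <- categorize_genes(expr)
  expect_equal(unname(cat), c("over_A", "over_B", "unchanged", "unchanged"))
  expect_error(categorize_genes(make_expr(c("g1", "g1"), c(1, 1),
                                          c(0.01, 0.01))), "duplicate")
})

test_that("top_differential matches a brute-force sort and warns when short", {
  set.seed(17)
  n <- 1000
  expr <- make_expr(sprintf("g%04d", 1:n),
                    log_fc = stats::rnorm(n, 0, 2),
                    adj_p = stats::runif(n, 0, 0.2))
  top <- top_differential(expr, n = 100, direction = "a")
  elig <- expr[expr$adj_p < 0.05 & expr$log_fc > 0, ]
  brute <- elig$gene_id[order(-abs(elig$log_fc), elig$gene_id)][1:100]
  expect_equal(top, brute)
  expect_warning(all_of_them <- top_differential(expr, n = n, "a"), "eligible")
  expect_equal(sort(all_of_them), sort(elig$gene_id))
})

test_that("universe arithmetic reproduces the 6,902-gene union", {
  n_a <- 3174; n_b <- 2670; n_both <- 1058
  expr <- make_expr(
    sprintf("g%05d", seq_len(n_a + n_b + n_both + 500)),
    log_fc = c(rep(1, n_a), rep(-1, n_b), rep(0.1, n_both), rep(0.1, 500)),
    adj_p = c(rep(0.01, n_a + n_b), rep(0.5, n_both + 500)),
    expressed_both = c(rep(FALSE, n_a + n_b), rep(TRUE, n_both),
                       rep(FALSE, 500))
  )
  expect_length(define_universe(expr), 6902)
  empty <- make_expr(character(0), numeric(0), numeric(0), logical(0))
  expect_length(define_universe(empty), 0)
})

test_that("window membership is strict and deduplicated", {
  genes <- gene_models(tibble::tibble(
    gene_id = c("edge", "near", "far"), chrom = "chr1",
    start = c(120000, 15000, 500000), end = c(130000, 25000, 510000),
    strand = "+"
  ))
  loci <- genomic_intervals(rep("chr1", 3), c(9500, 10500, 19500),
                            c(10501, 11501, 20501))
  res <- genes_within_window(loci, genes, window = 100e3)
  # "edge" TSS at 120000 is exactly 100 kb from its nearest midpoint
  # (20000) -> excluded under the strict inequality
  expect_false("edge" %in% res$gene_id)
  expect_false("far" %in% res$gene_id)
  # "near" is close to all three loci but appears once with min distance
  expect_equal(sum(res$gene_id == "near"), 1L)
  expect_equal(res$min_dist[res$gene_id == "near"], 4000)
})

test_that("window membership agrees with an all-pairs scan", {
  set.seed(23)
  n_g <- 1000; n_l <- 1000
  genes <- gene_models(tibble::tibble(
    gene_id = sprintf("g%04d", 1:n_g),
    chrom = sample(c("chr1", "chr2"), n_g, replace = TRUE),
    start = s <- sample.int(5e7, n_g), end = s + 1000L,
    strand = sample(c("+", "-"), n_g, replace = TRUE)
  ))
  loci <- genomic_intervals(sample(c("chr1", "chr2"), n_l, replace = TRUE),
                            s2 <- sample.int(5e7, n_l), s2 + 1000L)
  w <- 250e3
  res <- genes_within_window(loci, genes, w)
  mid <- interval_midpoint(loci)
  g <- genes$genes
  brute <- lapply(seq_len(n_g), function(i) {
    d <- abs(g$tss[i] - mid[loci$chrom == g$chrom[i]])
    if (length(d) && min(d) < w) min(d) else NULL
  })
  keep <- !vapply(brute, is.null, TRUE)
  expect_equal(res$gene_id, g$gene_id[keep])
  expect_equal(res$min_dist, unlist(brute[keep]))
})

test_that("window_scan counts are monotone and rings partition the genes", {
  ds <- small_dataset()
  loci <- loci_cols(ds$enhancers[ds$enhancers$cell == "A", ])
  ws <- window_scan(loci, ds$genes, ds$expression)
  expect_true(all(diff(ws$n_genes) >= 0))
  expect_true(all(diff(ws$over_a) >= 0))
  expect_equal(ws$over_a + ws$over_b + ws$unchanged, ws$n_genes)
  expect_error(window_scan(loci, ds$genes, ds$expression,
                           windows = c(2e5, 1e5)), "ascending")

  rings <- interval_scan(loci, ds$genes, ds$expression,
                         boundaries = c(0, 50e3, 100e3, 500e3, 2e6))
  expect_equal(sum(rings$n_genes),
               ws$n_genes[ws$window == 2e6])
  one_ring <- interval_scan(loci, ds$genes, ds$expression,
                            boundaries = c(0, 2e6))
  expect_equal(one_ring$n_genes, ws$n_genes[ws$window == 2e6])
  expect_equal(one_ring$over_a, ws$over_a[ws$window == 2e6])
})

test_that("window_scan tests in-window counts against a comparison set", {
  ds <- small_dataset()
  loci <- loci_cols(ds$enhancers[ds$enhancers$cell == "A", ])
  uni <- define_universe(ds$expression)
  ctrl <- sample_controls(uni, n = 150, seed = 2)
  ws <- window_scan(loci, ds$genes, ds$expression, windows = c(100e3),
                    comparison = ctrl)
  cat <- categorize_genes(ds$expression)
  manual <- chi_square_2x2(ws$over_a, ws$over_b,
                           sum(cat[ctrl] == "over_A"),
                           sum(cat[ctrl] == "over_B"))
  expect_equal(ws$p_value, manual$p_value)
})

test_that("an empty window is flagged rather than an error", {
  genes <- gene_models(tibble::tibble(
    gene_id = "g1", chrom = "chr1", start = 5e6, end = 5.01e6, strand = "+"
  ))
  expr <- make_expr("g1", 1, 0.01)
  loci <- genomic_intervals("chr2", 1000, 2001)
  ws <- window_scan(loci, genes, expr, windows = c(20e3, 50e3))
  expect_true(all(ws$empty))
  expect_true(all(is.na(ws$ratio_a_b)))
})

test_that("enrichment ratios reproduce the printed arithmetic", {
  expect_equal(enrichment_ratio(109, 54), 2.0)
  expect_equal(enrichment_ratio(104, 55), 1.9)
  expect_equal(enrichment_ratio(50, 50), 1.0)
  expect_error(enrichment_ratio(10, 0), "positive")
})

test_that("direct simulation CI collapses at the extremes", {
  flags0 <- stats::setNames(rep(FALSE, 500), sprintf("g%03d", 1:500))
  ci0 <- direct_simulation_ci(flags0, n = 100, k = 200, seed = 1)
  expect_equal(c(ci0$ci_low, ci0$ci_high), c(0L, 0L))
  flags1 <- !flags0
  ci1 <- direct_simulation_ci(flags1, n = 100, k = 200, seed = 1)
  expect_equal(c(ci1$ci_low, ci1$ci_high), c(100L, 100L))
  expect_error(direct_simulation_ci(flags0, n = 600), "exceeds")
})

test_that("direct simulation is seed-reproducible", {
  set.seed(99)
  flags <- stats::runif(1000) < 0.3
  a <- direct_simulation_ci(flags, n = 100, k = 500, seed = 7)
  b <- direct_simulation_ci(flags, n = 100, k = 500, seed = 7)
  expect_identical(a$counts, b$counts)
  c2 <- direct_simulation_ci(flags, n = 100, k = 500, seed = 8)
  expect_false(identical(a$counts, c2$counts))
})

test_that("simulated CI approaches the hypergeometric quantiles", {
  flags <- rep(c(TRUE, FALSE), c(300, 700))
  ci <- direct_simulation_ci(flags, n = 100, k = 20000, seed = 5)
  lo <- stats::qhyper(0.025, 300, 700, 100)
  hi <- stats::qhyper(0.975, 300, 700, 100)
  expect_lte(abs(ci$ci_low - lo), 1)
  expect_lte(abs(ci$ci_high - hi), 1)
})

test_that("control sampling is seeded, exclusive and uniform", {
  uni <- sprintf("g%04d", 1:2000)
  s1 <- sample_controls(uni, 300, seed = 4)
  s2 <- sample_controls(uni, 300, seed = 4)
  expect_identical(s1, s2)
  excl <- uni[1:1500]
  s3 <- sample_controls(uni, 300, seed = 4, exclude = excl)
  expect_length(intersect(s3, excl), 0)
  expect_error(sample_controls(uni, 600, exclude = excl), "too small")
  # frequencies roughly uniform across many seeds
  hits <- table(unlist(lapply(1:200, function(s) {
    sample_controls(uni[1:100], 10, seed = s)
  })))
  expect_gt(min(hits), 2)
})
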