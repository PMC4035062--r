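# enhancerlink

Distal regulatory elements (enhancers) carry characteristic histone marks —
H3K4me1 at enhancers generally, H3K27Ac at *active* enhancers — and are
often nucleosome-depleted (detectable by FAIRE). `enhancerlink` implements a
complete pipeline for asking how cell-type-specific enhancers relate to
nearby gene expression in a two-cell-type comparison (for example a normal
epithelial line versus a tumour-derived line):

1. **Cell-type-specific enhancer calling.** Candidate loci are tested for
   differential H3K4me1 tag density between the two cell types with an
   exact two-sample Poisson rate test (library sizes as exposures),
   Benjamini–Hochberg adjusted and gated at FDR ≤ 0.1 %; the top *N*
   (default 2,000) loci per cell type by fold-change of normalized tags
   (tags per 10⁷, `log2((norm_a + 1)/(norm_b + 1))`) form the specific
   sets, plus a "shared" control set of loci with the most similar density
   in both cell types.
2. **Poised vs active classification.** Loci are split by exact
   one-dimensional 2-means on normalized H3K27Ac density in ±1 kb of the
   locus midpoint (the globally optimal contiguous split of the sorted
   features, so the result is deterministic); the higher-density cluster is
   "active". FAIRE peak intersection flags nucleosome-depleted loci.
3. **Expression association.** Genes are categorized at the adjusted-p
   < 0.05 gate as overexpressed in A, overexpressed in B, or unchanged.
   Window scans (±20 kb up to ±2 Mb of locus midpoints, strict TSS
   distance) count categories among nearby genes; the over-A/over-B ratio
   and a 2×2 chi-square against a control set quantify enrichment. The
   null for "how many of the top-300 differential genes carry an enhancer
   within 100 kb" is computed by direct simulation: *k* = 100,000 random
   gene sets of size 300 drawn from the expression universe, with an
   empirical 95 % interval.
4. **Motif enrichment.** Region sequences are scanned with log-odds PWMs
   at an exact score-distribution p-value threshold (dynamic programme
   over discretized per-column score distributions; default p = 1e-4,
   both strands), and per-motif region counts between the two sets are
   compared by Pearson 2×2 chi-square without continuity correction:
   `X² = N(ad − bc)² / ((a+b)(c+d)(a+c)(b+d))`.
5. **Target genes.** Genes within 100 kb of both cell types' enhancer sets
   are excluded; active enhancers are then linked to concordantly
   overexpressed genes within 100 kb (many-to-many), with per-term 2×2
   chi-square comparison of the resulting gene sets (−log2 p reported).

A fully seeded synthetic-data generator (`synthetic_config()`,
`generate_dataset()`) plants ground truth for every stage — differential
tag enrichment, bimodal H3K27Ac, ~50 % FAIRE-positive loci,
distance-decaying enhancer–expression coupling, set-specific motif rates,
and a biased annotation term — so the whole pipeline is testable without
any external data.

## Worked example

```r
library(enhancerlink)

cfg <- synthetic_config(chrom_sizes = c(chr1 = 1e8, chr2 = 1e8),
                        n_genes = 2000, n_specific_enhancers_per_type = 150,
                        n_shared_enhancers = 100, tag_depth = 5e5, seed = 7)
ds <- generate_dataset(cfg)

cand  <- differential_loci(ds$tracks$k4me1_a, ds$tracks$k4me1_b,
                           ds$enhancers[, c("chrom", "start", "end", "name")])
sel_a <- select_top_specific(cand, n = 150, direction = "a")

table(classify_poised_active(sel_a, ds$tracks$k27ac_a)$state)
#> active poised
#>     74     76

window_scan(sel_a, ds$genes, ds$expression)[, c("window", "n_genes",
                                                "over_a", "over_b",
                                                "ratio_a_b")]
#>    window n_genes over_a over_b ratio_a_b
#> 1   20000      76     38     32      1.19
#> 2   50000     195    120     53      2.26
#> 3  100000     338    196    103      1.90
#> ...
#> 8 2000000    1950    676    642      1.05

uni   <- define_universe(ds$expression)
flags <- setNames(uni %in% genes_within_window(sel_a, ds$genes)$gene_id, uni)
direct_simulation_ci(flags, n = 300, k = 10000, seed = 42)
#> direct-simulation null: k = 10000 , n = 300 , 95% CI [ 39 , 63 ]

top_a <- top_differential(ds$expression, n = 300, direction = "a")
sum(top_a %in% names(flags)[flags])
#> [1] 80
```

Reading: about half the called A-specific enhancers are active; the
over-A/over-B ratio among nearby genes decays from ~1.9 at ±100 kb toward
1 at ±2 Mb (the planted coupling has a 250 kb scale); and 80 of the top
300 A-overexpressed genes lie within 100 kb of a called enhancer, far
above the resampling null of 39–63 — the planted enhancer–expression link
is recovered.

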