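---
title: "Methods: enhancer calling, state classification and expression linkage"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: enhancer calling, state classification and expression linkage}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(enhancerlink)
```

This vignette documents the statistical procedures, the tunable
parameters and their defaults, the synthetic-data model used for
validation, and the design decisions taken where the methodology was
genuinely open. It states no empirical result beyond what the package's
test suite and acceptance script themselves compute.

## Coordinates and containers

All intervals are BED-convention 0-based half-open `[start, end)`;
midpoints are `floor((start + end)/2)`. Gene models carry a strand-aware
TSS (`start` for `+` genes, `end − 1` for `−` genes); every
enhancer–gene distance in the package is `|TSS − locus midpoint|`, with a
*strict* inequality at window edges. The anchor choice (midpoint rather
than interval edge) gives a single unambiguous distance per pair and
makes window membership independent of locus width. Tag data are stored
as sorted per-chromosome tag positions plus a library size; all densities
are normalized to tags per 10⁷.

## Differential enhancer calling

At each candidate locus, tags are counted in a ±`flank` window around the
midpoint (default 500 bp — candidate loci are upstream peak calls, so one
kilobase captures the mark's local pileup). The two counts are compared
with the exact two-sample Poisson rate test, conditioning on the total:
given `a + b` tags, `a` is binomial with success probability
`lib_a/(lib_a + lib_b)` under the null of equal rates
(`stats::poisson.test` with library sizes as exposures). This exact
conditional form is used instead of a one-sample Poisson tail against the
scaled opposite count because the latter is undefined when that count is
zero, which is routine at sequencing-scale background. P-values are
Benjamini–Hochberg adjusted; the significance gate is FDR ≤ 0.001 (a
0.10 % false discovery rate).

Fold-change is `log2((norm_a + 1)/(norm_b + 1))` with a pseudocount of 1
on the tags-per-10⁷ scale to avoid division by zero. Specific sets take
the top *n* = 2,000 gated loci per direction, sorted by fold-change with
ties broken by the favoured cell's normalized count and then coordinate
order, so selections are bit-reproducible. The two specific sets are
disjoint by construction (opposite fold-change signs). The shared set
takes the *n* loci with the smallest |log2 fold-change| among loci whose
normalized density exceeds `min_norm` in *both* cells (default 50 tags
per 10⁷ per window); the gate exists because a locus with no signal in
either cell also has fold-change ≈ 0 but is not an enhancer.

## Poised vs active classification

The published approach clusters H3K27Ac tag profiles with K-means
(n = 2). K-means with random initialization is seed-dependent, and Lloyd
iteration from any fixed initialization can stall in a local optimum, so
this package solves the 1-D 2-means problem *exactly*: for scalar
features the optimal two clusters are contiguous in sorted order, so
scanning all n − 1 splits of the sorted features for minimal total
within-cluster sum of squares finds the global optimum in O(n log n).
The per-locus feature is the normalized H3K27Ac count in ±1 kb of the
midpoint; the cluster with the higher mean is labelled *active*. The
feature is a scalar summary rather than a binned vector for determinism
and testability; the split is identical whenever the summary orders loci
the same way as the profile intensity. Identical features across all
loci are a degenerate-clustering error rather than an arbitrary split.

FAIRE (nucleosome-depletion) flags are set when the locus midpoint ±500 bp
overlaps any FAIRE peak by ≥ 1 bp; the slop absorbs the offset between
histone-mark pileups and the depleted region between them.

## Expression association

Genes are categorized at adjusted p < 0.05 (strict) with the fold-change
sign deciding the direction; `adj_p = 0.05` exactly is *unchanged*. The
"top differential" selection ranks significant genes of one direction by
|log fold-change| with gene-id tie-breaks and takes *n* = 300. The
expression universe for control sampling is the union of both
overexpressed sets and the genes expressed in both conditions
(the structure of a 3,174 + 2,670 + 1,058 = 6,902-gene universe).

Window scans count gene categories within ±w of any locus midpoint for
an ascending ladder, default {20 kb, 50 kb, 100 kb, 250 kb, 500 kb,
750 kb, 1 Mb, 2 Mb} — eight sizes with the published endpoints; the
intermediate values are configurable since only the endpoints are fixed
by convention. Each gene counts once per window regardless of enhancer
multiplicity. Ring (distance-interval) scans assign each gene to the
single ring containing its minimal distance. Between-group enrichment
uses the Pearson 2×2 chi-square without continuity correction
(`X² = N(ad − bc)²/((a+b)(c+d)(a+c)(b+d))`, df = 1); the uncorrected form
reproduces published motif-table p-values from their printed counts,
which fixes the convention.

The "direct simulation" null resamples gene sets: *k* replicates
(default 100,000) of *n* genes drawn without replacement from the
universe, counting genes flagged as enhancer-adjacent. The resampling
unit is the gene (not the probe or the locus): it is the only unit for
which the observed statistic — a count over a selected gene set — has a
directly comparable null. The 95 % interval is the empirical 2.5th/97.5th
percentile (type-7 linear interpolation) rounded *outward* to integers;
the rounding direction is conservative and documented for
bit-reproducibility. With uniform sampling this null is hypergeometric,
which the test suite uses as a closed-form oracle. If probe-level
expression is supplied upstream, the probe with the smallest adjusted p
should represent its gene before any of these steps.

## Motif enrichment

PFMs (JASPAR text or minimal MEME format) become log-odds PWMs via
`score(b,i) = log2(((count(b,i) + pc·bg_b)/(colsum_i + pc))/bg_b)` with a
total pseudocount `pc = 0.1` spread by background frequency. The
score-threshold for a target p-value is computed exactly: per-column
score distributions under the 0-order background are discretized at
ε = 0.01 log2-odds units and convolved by dynamic programming, giving the
full match-score distribution; the threshold is the smallest achievable
score whose upper tail is ≤ p (default 1e-4, the standard scanner output
threshold). The discretization error is bounded by w·ε/2 in score units
(≤ 0.1 for a 20-column motif); scanning rounds window scores to the same
grid so threshold and scan are mutually consistent. Both strands are
scanned (reverse-complemented matrix); windows containing `N` are
skipped; a region counts once if it contains ≥ 1 hit. Short motifs may
have no achievable score with tail ≤ 1e-4 (a perfect 6-mer match already
has probability 0.25⁶ ≈ 2.4e-4 under uniform background); the threshold
then falls back to the maximum achievable score with a warning.

Enrichment between two region sets tests, per motif, regions-with-hit vs
regions-without in a 2×2 chi-square. The region-count (not
occurrence-count) convention is adopted because it reproduces the
published table's verifiable row from its printed totals. No
multiple-testing correction is applied to the motif table — the published
convention is a raw p < 0.05 filter — but a BH-adjusted column is emitted
for users who want it.

## Target genes and term enrichment

Genes within 100 kb of both specific sets are excluded (clustered
enhancers of both cell types would otherwise claim the same genes); among
the remainder, each *active* enhancer is linked to every concordantly
overexpressed gene within 100 kb. Multiplicity is reported as full degree
histograms in both directions. Term-set comparison between two gene sets
is a per-term 2×2 chi-square with −log2 p reported; the significance
threshold is a flag (default 0.05, since published analyses use values
between 0.02 and 0.03 depending on the comparison). Control gene sets for
term comparisons are drawn with `sample_controls()` under a dedicated
seed.

## The synthetic-data model

`synthetic_config()` defines a seeded world; identical seeds give
identical datasets, and each generator stage takes its own derived seed
so stages can be regenerated independently (e.g. fresh expression tables
over a fixed annotation for replicate studies).

* **Genome and annotation.** Default four chromosomes totalling 1.8 Gb —
  scaled so that a 2,000-locus enhancer set with ±100 kb windows covers
  roughly 20 % of the default 6,902-gene universe, echoing the ~1,400 of
  6,902 structure of the motivating data. TSSs are uniform with random
  strand; gene spans are 5–50 kb with 1–3 non-overlapping exons.
* **Enhancers.** 2,000 specific loci per cell type plus 2,000 shared, on
  a slot grid guaranteeing ≥ 1 kb separation; a configured fraction
  (default 0.5) of specific loci is forced within 100 kb of some TSS
  (with collision retries), the rest uniform. Labels: active with
  probability `p_active` (0.5), nucleosome-depleted with `p_faire` (0.5),
  independent of each other.
* **Tags.** Uniform background (2e6 tags per track) plus, at each planted
  locus, a symmetric triangular pileup (half-width 150 bp, echoing an
  upstream caller's triangle model) with expected count `signal_ratio`
  (default 60) times the background expectation in a 1 kb window — the
  published fold difference at specific loci. H3K4me1 signal at specific
  (matching cell) and shared (both cells) loci; H3K27Ac only at active
  loci; FAIRE at depleted loci of either state.
* **Expression.** A single uniform draw per gene against
  `pA = coupling(dA)` and `pB = coupling(dB)` (distances to the nearest
  A-/B-specific enhancer; probabilities rescaled only if their sum
  exceeds 1) gives exact marginal category probabilities: a flat coupling
  yields distance-independent categories, and coupling 1 at d = 0 makes
  the matching category certain. Default coupling
  `0.5·exp(−d/250 kb) + 0.2`: strong enrichment at 100 kb, effectively
  gone by ~750 kb, matching the qualitative range over which enhancer
  effects are expected to decay. Differential genes get adjusted
  p < 0.05 and sign-consistent log fold-changes; expression is generated
  at gene level (probe-level replication is out of scope).
* **Sequences and terms.** Region sequences are i.i.d. uniform
  nucleotides with a consensus motif (default `TGACTCA`, an AP-1-style
  7-mer) planted once per region with set-specific probability (defaults
  0.4 vs 0.05) at a random offset and strand. Every gene receives two
  uniform background terms; one enriched term is added with probability
  0.4 for genes within 100 kb of an A-specific enhancer and 0.1
  otherwise. The shipped motif library
  (`inst/extdata/motifs_synthetic.jaspar`) is a synthetic,
  consensus-derived example set, not a copy of any curated database.

What the generator does **not** emulate: mappability and GC bias,
replicate structure, peak-width variation, chromatin domains/3-D
clustering, correlated gene neighbourhoods, and probe-level microarray
noise. Passing tests therefore demonstrate that the pipeline's inference
is correct when its model assumptions hold, not that those assumptions
hold in any particular real dataset.

## Validation strategy and problem sizes

Every non-trivial operation is checked against an independent oracle:
the chi-square against `stats::chisq.test(correct = FALSE)`; the exact
1-D 2-means against an exhaustive split scan and `stats::kmeans` with
multiple restarts; the PWM threshold DP against complete k-mer
enumeration for widths ≤ 6; window assignment against an all-pairs scan
(1,000 genes × 1,000 loci); the simulation null against closed-form
hypergeometric quantiles (6,902-gene universe, k = 100,000); and the
differential test against a hand-summed conditional binomial tail.
Planted-truth recovery runs on a dense world (600 specific enhancers per
type, 6,000 genes, step coupling 0.4 within 100 kb vs 0.2 baseline, 100
expression replicates) and the distance-decay profile on a sparse world
(60 enhancers per type over 600 Mb) where window coverage keeps growing
to ±2 Mb, so the expected over-A/over-B ratio strictly decreases across
the ladder; the profile is averaged over the 100 replicates because
adjacent windows whose expected gap is below counting noise need not be
ordered in any single draw. Null calibration (flat coupling; symmetric
motif rates 0.3/0.3) uses 200 replicates and checks the per-test
rejection rate against binomial bounds around the nominal 5 %. These
problem sizes were chosen as the smallest worlds in which the planted
effects are statistically unambiguous.

## Known limitations

* Candidate loci are an input; peak calling from raw tags is out of
  scope, as are read alignment and array preprocessing.
* The shared-set background gate `min_norm` is depth- and
  window-dependent; the default (50 tags per 10⁷ per 1 kb window) suits
  libraries where planted/true signal exceeds background several-fold,
  and should be re-derived for very shallow or very deep libraries.
* The 0-order background for motif scanning is estimated or supplied
  globally; higher-order (di-nucleotide) backgrounds are not modelled.
* The exact 2-means split assumes the H3K27Ac summary is the quantity of
  interest; profiles whose shape (not level) distinguishes states would
  need the vector variant.
* Chi-square p-values are asymptotic; for very small expected counts the
  enrichment table should be read with the usual caution.
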