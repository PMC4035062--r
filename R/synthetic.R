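#' Configuration for the synthetic dataset generator
#'
#' Defines a seeded synthetic world with planted ground truth: two cell types
#' ("A" and "B", standing for a normal and a tumour-derived epithelial line),
#' cell-type-specific and shared enhancer loci, H3K4me1/H3K27Ac/FAIRE tag
#' tracks, a two-condition expression table coupled to enhancer distance,
#' region sequences with planted motifs, and a gene-to-term map with one
#' biased term.
#'
#' @param chrom_sizes Named numeric vector of chromosome lengths in bp.
#' @param n_genes Number of genes (the expression universe).
#' @param n_specific_enhancers_per_type Planted specific enhancers per cell
#'   type.
#' @param n_shared_enhancers Planted shared enhancers (similar density in
#'   both cell types).
#' @param locus_width Width of each planted locus in bp.
#' @param p_active Fraction of planted enhancers that carry H3K27Ac
#'   ("active"); the remainder are "poised".
#' @param p_faire Fraction of planted enhancers that are nucleosome-depleted
#'   (carry FAIRE signal), independent of state.
#' @param p_near_tss Fraction of specific enhancers forced to lie within
#'   100 kb of some TSS (the rest are placed uniformly).
#' @param coupling_prob Function of distance d (bp) giving the probability
#'   that a gene is overexpressed in the cell type matching its nearest
#'   specific enhancer. Must be non-increasing; its value at large d is the
#'   baseline shared by all genes.
#' @param tag_depth Background tags per track (library depth before planted
#'   signal is added).
#' @param signal_ratio Planted locus tag density as a multiple of the local
#'   background density (per matching cell type).
#' @param peak_half_width Half-width in bp of the triangular tag pileup at
#'   planted loci.
#' @param motif_consensus Consensus sequence of the planted motif.
#' @param motif_rate_pair Length-2 numeric: probability that a region from
#'   set A / set B carries one planted motif occurrence.
#' @param n_terms Size of the term vocabulary for the gene-to-term map.
#' @param term_rate_pair Length-2 numeric: probability that an A-linked /
#'   other gene is annotated with the single enriched term.
#' @param seed Integer seed; identical seeds give identical datasets.
#'
#' @return A list of class `synthetic_config`.
#' @export
synthetic_config <- function(chrom_sizes = c(chr1 = 5e8, chr2 = 5e8,
                                             chr3 = 4e8, chr4 = 4e8),
                             n_genes = 6902,
                             n_specific_enhancers_per_type = 2000,
                             n_shared_enhancers = 2000,
                             locus_width = 1000,
                             p_active = 0.5,
                             p_faire = 0.5,
                             p_near_tss = 0.5,
                             coupling_prob = function(d) {
                               0.5 * exp(-d / 250e3) + 0.2
                             },
                             tag_depth = 2e6,
                             signal_ratio = 60,
                             peak_half_width = 150,
                             motif_consensus = "TGACTCA",
                             motif_rate_pair = c(0.4, 0.05),
                             n_terms = 20,
                             term_rate_pair = c(0.4, 0.1),
                             seed = 1L) {
  probs <- c(p_active = p_active, p_faire = p_faire, p_near_tss = p_near_tss,
             motif_rate_pair, term_rate_pair)
  if (any(probs < 0) || any(probs > 1)) {
    stop("all probability parameters must lie in [0, 1]")
  }
  grid <- seq(0, 5e6, length.out = 200)
  cp <- vapply(grid, coupling_prob, 1)
  if (any(cp < 0) || any(cp > 1)) stop("coupling_prob must map into [0, 1]")
  if (any(diff(cp) > 1e-12)) stop("coupling_prob must be non-increasing")
  if (tag_depth <= 0) stop("tag_depth must be positive")
  if (is.null(names(chrom_sizes))) stop("chrom_sizes must be named")
  structure(list(
    chrom_sizes = chrom_sizes, n_genes = n_genes,
    n_specific_enhancers_per_type = n_specific_enhancers_per_type,
    n_shared_enhancers = n_shared_enhancers, locus_width = locus_width,
    p_active = p_active, p_faire = p_faire, p_near_tss = p_near_tss,
    coupling_prob = coupling_prob, tag_depth = tag_depth,
    signal_ratio = signal_ratio, peak_half_width = peak_half_width,
    motif_consensus = toupper(motif_consensus),
    motif_rate_pair = motif_rate_pair, n_terms = n_terms,
    term_rate_pair = term_rate_pair, seed = as.integer(seed)
  ), class = "synthetic_config")
}

# Sample n free slots from a genome-wide slot grid; slots are locus-sized
# cells separated by >= 1 kb by construction.
.slot_grid <- function(chrom_sizes, locus_width) {
  slot_w <- locus_width + 1500
  n_slots <- floor(chrom_sizes / slot_w)
  list(slot_w = slot_w, n_slots = n_slots,
       offsets = c(0, cumsum(n_slots))[seq_along(n_slots)],
       total = sum(n_slots))
}

.slot_to_interval <- function(grid, slot_idx, chrom_sizes, locus_width) {
  chrom_idx <- findInterval(slot_idx - 0.5, c(0, cumsum(grid$n_slots)))
  local <- slot_idx - grid$offsets[chrom_idx] - 1L
  start <- local * grid$slot_w + 750
  tibble::tibble(chrom = names(chrom_sizes)[chrom_idx],
                 start = as.integer(start),
                 end = as.integer(start + locus_width))
}

#' Generate a synthetic gene annotation and planted enhancer loci
#'
#' TSSs are placed uniformly with random strand; specific enhancers are
#' placed on a non-overlapping slot grid (>= 1 kb apart), with a configured
#' fraction forced within 100 kb of some TSS. Deterministic per seed.
#'
#' @param config A [synthetic_config()].
#' @param seed Seed; defaults to `config$seed`.
#' @return A list with `genes` (a [gene_models()] object) and `enhancers`
#'   (interval tibble with hidden-truth columns `cell`
#'   (`"A"`/`"B"`/`"shared"`), `state` (`"active"`/`"poised"`), `faire`).
#' @export
generate_annotation <- function(config, seed = config$seed) {
  stopifnot(inherits(config, "synthetic_config"))
  set.seed(seed)
  cs <- config$chrom_sizes
  genome <- sum(cs)
  # genes
  n_genes <- config$n_genes
  genes <- NULL
  if (n_genes > 0) {
    chrom <- sample(names(cs), n_genes, replace = TRUE, prob = cs / genome)
    len <- round(stats::runif(n_genes, 5e3, 5e4))
    tss <- floor(stats::runif(n_genes) * (cs[chrom] - 2 * len - 2)) + len + 1
    strand <- sample(c("+", "-"), n_genes, replace = TRUE)
    start <- ifelse(strand == "+", tss, tss + 1 - len)
    genes_tbl <- tibble::tibble(
      gene_id = sprintf("gene_%05d", seq_len(n_genes)),
      chrom = chrom, start = as.integer(start),
      end = as.integer(start + len), strand = strand
    )
    # 1-3 exons per gene, non-overlapping thirds of the span
    n_ex <- sample(1:3, n_genes, replace = TRUE)
    ex <- lapply(seq_len(n_genes), function(i) {
      k <- n_ex[i]
      seg <- floor((genes_tbl$end[i] - genes_tbl$start[i]) / (2 * k))
      s <- genes_tbl$start[i] + (seq_len(k) - 1L) * 2L * seg
      tibble::tibble(gene_id = genes_tbl$gene_id[i],
                     chrom = genes_tbl$chrom[i],
                     start = as.integer(s),
                     end = as.integer(s + pmax(seg, 200L)))
    })
    genes <- gene_models(genes_tbl, do.call(rbind, ex))
  } else {
    genes <- gene_models(tibble::tibble(
      gene_id = character(), chrom = character(), start = integer(),
      end = integer(), strand = character()
    ))
  }
  # enhancer slots
  n_spec <- config$n_specific_enhancers_per_type
  n_total <- 2L * n_spec + config$n_shared_enhancers
  grid <- .slot_grid(cs, config$locus_width)
  if (n_total > grid$total * 0.8) {
    stop("capacity error: ", n_total, " loci requested but only ",
         grid$total, " non-overlapping slots available")
  }
  taken <- integer(0)
  slots <- integer(n_total)
  # forced-near-TSS quota for the specific enhancers
  n_near <- if (n_genes > 0) round(config$p_near_tss * 2L * n_spec) else 0L
  tss_all <- genes$genes$tss
  tss_chrom <- genes$genes$chrom
  chrom_offset <- stats::setNames(grid$offsets, names(cs))
  filled <- 0L
  if (n_near > 0L) {
    taken_set <- new.env(parent = emptyenv())
    for (j in seq_len(n_near)) {
      # retry a few times on slot collisions so the forced quota is met
      for (try in 1:50) {
        g_idx <- sample.int(n_genes, 1L)
        pos <- tss_all[g_idx] + round(stats::runif(1, -95e3, 95e3))
        pos <- min(max(pos, 0), cs[[tss_chrom[g_idx]]] - config$locus_width)
        slot <- chrom_offset[[tss_chrom[g_idx]]] + pos %/% grid$slot_w + 1L
        key <- as.character(slot)
        if (is.null(taken_set[[key]])) {
          taken_set[[key]] <- TRUE
          filled <- filled + 1L
          slots[filled] <- slot
          break
        }
      }
    }
    taken <- slots[seq_len(filled)]
  }
  if (filled < n_total) {
    remaining <- setdiff(seq_len(grid$total), taken)
    slots[(filled + 1L):n_total] <- sample(remaining, n_total - filled)
  }
  # shuffle so truth labels are independent of placement mechanism
  slots <- sample(slots)
  iv <- .slot_to_interval(grid, slots, cs, config$locus_width)
  cell <- c(rep("A", n_spec), rep("B", n_spec),
            rep("shared", config$n_shared_enhancers))
  enhancers <- tibble::tibble(
    chrom = iv$chrom, start = iv$start, end = iv$end,
    name = sprintf("enh_%05d", seq_len(n_total)),
    cell = cell,
    state = ifelse(stats::runif(n_total) < config$p_active,
                   "active", "poised"),
    faire = stats::runif(n_total) < config$p_faire
  )
  list(genes = genes, enhancers = enhancers)
}

# Draw planted tags at loci: triangular pileup at midpoints, Poisson counts
# scaled to `ratio` times the local background window density.
.planted_tags <- function(loci, ratio, lambda_bg, half_width) {
  if (nrow(loci) == 0L) return(tibble::tibble(chrom = character(),
                                              pos = numeric()))
  mid <- interval_midpoint(loci)
  n <- stats::rpois(nrow(loci), ratio * lambda_bg)
  chrom <- rep(loci$chrom, n)
  pos <- rep(mid, n) + .triangular_offset(sum(n), half_width)
  tibble::tibble(chrom = chrom, pos = pos)
}

#' Generate synthetic tag tracks for both cell types
#'
#' Produces six tracks: H3K4me1, H3K27Ac and FAIRE for cell types A and B.
#' Background tags are uniform over the genome; each planted locus receives
#' extra tags from a symmetric triangular pileup centred at its midpoint,
#' with expected count `signal_ratio` times the background expectation in a
#' 1 kb window. H3K4me1 signal is added at specific loci (matching cell
#' only) and shared loci (both cells); H3K27Ac only at active loci; FAIRE at
#' nucleosome-depleted loci of either state.
#'
#' @param config A [synthetic_config()].
#' @param enhancers Truth enhancer tibble from [generate_annotation()].
#' @param seed Seed; defaults to `config$seed + 1`.
#' @return Named list of [tag_track()] objects: `k4me1_a`, `k4me1_b`,
#'   `k27ac_a`, `k27ac_b`, `faire_a`, `faire_b`.
#' @export
generate_tag_tracks <- function(config, enhancers,
                                seed = config$seed + 1L) {
  stopifnot(inherits(config, "synthetic_config"))
  if (config$tag_depth <= 0) stop("tag_depth must be positive")
  set.seed(seed)
  cs <- config$chrom_sizes
  genome <- sum(cs)
  lambda_bg <- config$tag_depth * 1000 / genome  # expected bg tags per 1 kb
  background <- function() {
    n_chr <- stats::rmultinom(1, config$tag_depth, cs / genome)[, 1]
    tibble::tibble(chrom = rep(names(cs), n_chr),
                   pos = floor(stats::runif(sum(n_chr)) * rep(cs, n_chr)))
  }
  sel <- function(cells, states = c("active", "poised"), faire_only = FALSE) {
    keep <- enhancers$cell %in% cells & enhancers$state %in% states
    if (faire_only) keep <- keep & enhancers$faire
    enhancers[keep, ]
  }
  mk <- function(loci_list) {
    tags <- rbind(background(),
                  do.call(rbind, lapply(loci_list, .planted_tags,
                                        ratio = config$signal_ratio,
                                        lambda_bg = lambda_bg,
                                        half_width = config$peak_half_width)))
    tag_track(split(tags$pos, factor(tags$chrom, levels = names(cs))))
  }
  list(
    k4me1_a = mk(list(sel(c("A", "shared")))),
    k4me1_b = mk(list(sel(c("B", "shared")))),
    k27ac_a = mk(list(sel(c("A", "shared"), states = "active"))),
    k27ac_b = mk(list(sel(c("B", "shared"), states = "active"))),
    faire_a = mk(list(sel(c("A", "shared"), faire_only = TRUE))),
    faire_b = mk(list(sel(c("B", "shared"), faire_only = TRUE)))
  )
}

#' Generate a synthetic two-condition expression table
#'
#' Each gene is assigned a category (overexpressed in A, overexpressed in B,
#' or unchanged) from a single uniform draw with probabilities
#' `pA = coupling_prob(dA)` and `pB = coupling_prob(dB)`, where `dA`/`dB` are
#' TSS distances to the nearest planted A-/B-specific enhancer midpoint (if
#' `pA + pB > 1` both are rescaled to sum to 1). Marginal category
#' probabilities therefore equal the coupling function exactly, and are
#' independent of enhancer distance when the coupling is flat. Differential
#' genes receive adjusted p < 0.05 and a log fold-change of matching sign.
#'
#' @param config A [synthetic_config()].
#' @param genes A [gene_models()] object.
#' @param enhancers Truth enhancer tibble.
#' @param seed Seed; defaults to `config$seed + 2`.
#' @return Tibble with columns `gene_id`, `mean_a`, `mean_b`, `log_fc`
#'   (A minus B), `adj_p`, `expressed_both`, plus hidden-truth column
#'   `category`.
#' @export
generate_expression <- function(config, genes, enhancers,
                                seed = config$seed + 2L) {
  stopifnot(inherits(config, "synthetic_config"),
            inherits(genes, "gene_models"))
  set.seed(seed)
  g <- genes$genes
  n <- nrow(g)
  if (n == 0L) {
    return(tibble::tibble(gene_id = character(), mean_a = numeric(),
                          mean_b = numeric(), log_fc = numeric(),
                          adj_p = numeric(), expressed_both = logical(),
                          category = character()))
  }
  enh_a <- enhancers[enhancers$cell == "A", ]
  enh_b <- enhancers[enhancers$cell == "B", ]
  d_a <- .nearest_distance(g$chrom, g$tss, enh_a$chrom,
                           interval_midpoint(enh_a))
  d_b <- .nearest_distance(g$chrom, g$tss, enh_b$chrom,
                           interval_midpoint(enh_b))
  p_a <- vapply(d_a, config$coupling_prob, 1)
  p_b <- vapply(d_b, config$coupling_prob, 1)
  tot <- p_a + p_b
  over <- tot > 1
  p_a[over] <- p_a[over] / tot[over]
  p_b[over] <- p_b[over] / tot[over]
  u <- stats::runif(n)
  category <- ifelse(u < p_a, "over_A",
                     ifelse(u < p_a + p_b, "over_B", "unchanged"))
  log_fc <- numeric(n)
  is_a <- category == "over_A"; is_b <- category == "over_B"
  log_fc[is_a] <- pmax(abs(stats::rnorm(sum(is_a), 1.5, 0.6)), 0.2)
  log_fc[is_b] <- -pmax(abs(stats::rnorm(sum(is_b), 1.5, 0.6)), 0.2)
  adj_p <- stats::runif(n, 0.05, 1)
  adj_p[is_a | is_b] <- stats::runif(sum(is_a | is_b), 0, 0.0499)
  mean_b <- 2^stats::rnorm(n, 5, 1)
  mean_a <- mean_b * 2^log_fc
  tibble::tibble(gene_id = g$gene_id, mean_a = mean_a, mean_b = mean_b,
                 log_fc = log_fc, adj_p = adj_p,
                 expressed_both = TRUE, category = category)
}

#' Generate region sequences with planted motifs and a gene-to-term map
#'
#' Region sequences (one per specific enhancer locus) are i.i.d. uniform
#' nucleotides with the configured motif consensus planted once per region
#' (random offset and strand) with set-specific probability
#' `motif_rate_pair[1]` for cell-A loci and `motif_rate_pair[2]` for cell-B
#' loci. The term map annotates every gene with two uniform background terms
#' and adds the single enriched term `TERM_enriched` with probability
#' `term_rate_pair[1]` for genes within 100 kb of an A-specific enhancer and
#' `term_rate_pair[2]` otherwise.
#'
#' @param config A [synthetic_config()].
#' @param genes A [gene_models()] object.
#' @param enhancers Truth enhancer tibble.
#' @param seed Seed; defaults to `config$seed + 3`.
#' @return List with `sequences` (named character vector, names =
#'   enhancer names), `motif_planted` (named logical), and `term_map`
#'   (tibble `gene_id`, `term_id`).
#' @export
generate_sequences_and_terms <- function(config, genes, enhancers,
                                         seed = config$seed + 3L) {
  stopifnot(inherits(config, "synthetic_config"))
  set.seed(seed)
  motif <- strsplit(config$motif_consensus, "")[[1]]
  w <- length(motif)
  width <- config$locus_width
  if (w > width) stop("motif longer than region width")
  spec <- enhancers[enhancers$cell %in% c("A", "B"), ]
  n <- nrow(spec)
  rate <- ifelse(spec$cell == "A", config$motif_rate_pair[1],
                 config$motif_rate_pair[2])
  planted <- stats::runif(n) < rate
  bases <- c("A", "C", "G", "T")
  comp <- c(A = "T", C = "G", G = "C", T = "A")
  rc <- paste(rev(comp[motif]), collapse = "")
  fwd <- paste(motif, collapse = "")
  seqs <- vapply(seq_len(n), function(i) {
    s <- sample(bases, width, replace = TRUE)
    if (planted[i]) {
      at <- sample.int(width - w + 1L, 1L)
      ins <- if (stats::runif(1) < 0.5) fwd else rc
      s[at:(at + w - 1L)] <- strsplit(ins, "")[[1]]
    }
    paste(s, collapse = "")
  }, "")
  names(seqs) <- spec$name
  names(planted) <- spec$name
  # term map
  g <- genes$genes
  term_map <- tibble::tibble(gene_id = character(), term_id = character())
  if (nrow(g) > 0L) {
    enh_a <- enhancers[enhancers$cell == "A", ]
    d_a <- .nearest_distance(g$chrom, g$tss, enh_a$chrom,
                             interval_midpoint(enh_a))
    linked <- d_a <= 100e3
    p_enr <- ifelse(linked, config$term_rate_pair[1], config$term_rate_pair[2])
    vocab <- sprintf("TERM_%02d", seq_len(config$n_terms))
    bg <- tibble::tibble(
      gene_id = rep(g$gene_id, each = 2L),
      term_id = sample(vocab, 2L * nrow(g), replace = TRUE)
    )
    enr <- tibble::tibble(
      gene_id = g$gene_id[stats::runif(nrow(g)) < p_enr],
      term_id = "TERM_enriched"
    )
    term_map <- unique(rbind(bg, enr))
  }
  list(sequences = seqs, motif_planted = planted, term_map = term_map)
}

#' Generate a complete synthetic dataset
#'
#' Runs all four generators with seeds derived from `config$seed`.
#'
#' @param config A [synthetic_config()].
#' @return List with `genes`, `enhancers`, `tracks`, `expression`,
#'   `sequences`, `motif_planted`, `term_map`, `config`.
#' @export
generate_dataset <- function(config = synthetic_config()) {
  ann <- generate_annotation(config)
  tracks <- generate_tag_tracks(config, ann$enhancers)
  expr <- generate_expression(config, ann$genes, ann$enhancers)
  st <- generate_sequences_and_terms(config, ann$genes, ann$enhancers)
  list(genes = ann$genes, enhancers = ann$enhancers, tracks = tracks,
       expression = expr, sequences = st$sequences,
       motif_planted = st$motif_planted, term_map = st$term_map,
       config = config)
}

#' Write a synthetic dataset to plain-text files
#'
#' Emits loci as BED, expression / term map / truth labels as TSV, and
#' region sequences as FASTA.
#'
#' @param dataset Output of [generate_dataset()].
#' @param outdir Output directory (created if needed).
#' @return `outdir`, invisibly.
#' @export
write_dataset <- function(dataset, outdir) {
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  enh <- dataset$enhancers
  write_bed(enh[, c("chrom", "start", "end", "name")],
            file.path(outdir, "enhancers.bed"))
  write_tsv_table(enh, file.path(outdir, "enhancers_truth.tsv"))
  write_tsv_table(dataset$genes$genes, file.path(outdir, "genes.tsv"))
  write_tsv_table(dataset$expression, file.path(outdir, "expression.tsv"))
  write_tsv_table(dataset$term_map, file.path(outdir, "term_map.tsv"))
  write_region_fasta(dataset$sequences, file.path(outdir, "regions.fa"))
  invisible(outdir)
}
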