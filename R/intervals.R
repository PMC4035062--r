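#' Construct a set of genomic intervals
#'
#' Intervals follow the BED convention throughout the package: 0-based,
#' half-open `[start, end)`. Midpoints are `floor((start + end) / 2)`.
#'
#' @param chrom Character vector of chromosome names (non-empty strings).
#' @param start Integer vector of 0-based inclusive start positions.
#' @param end Integer vector of exclusive end positions; must satisfy
#'   `start < end`.
#' @param name Optional character vector of labels.
#' @param score Optional numeric vector.
#' @param strand Optional strand vector with values in `"+"`, `"-"`, `"*"`
#'   (unstranded).
#'
#' @return A tibble with columns `chrom`, `start`, `end` and any of `name`,
#'   `score`, `strand` that were supplied.
#' @export
genomic_intervals <- function(chrom, start, end, name = NULL, score = NULL,
                              strand = NULL) {
  chrom <- as.character(chrom)
  start <- as.integer(start)
  end <- as.integer(end)
  if (any(is.na(chrom)) || any(!nzchar(chrom))) {
    stop("chromosome names must be non-empty")
  }
  if (any(is.na(start)) || any(is.na(end))) {
    stop("interval coordinates must be integers")
  }
  if (any(start < 0L)) stop("interval starts must be >= 0")
  if (any(start >= end)) stop("intervals must satisfy start < end")
  out <- tibble::tibble(chrom = chrom, start = start, end = end)
  if (!is.null(name)) out$name <- as.character(name)
  if (!is.null(score)) out$score <- as.numeric(score)
  if (!is.null(strand)) {
    strand <- as.character(strand)
    if (!all(strand %in% c("+", "-", "*"))) {
      stop("strand must be one of '+', '-', '*'")
    }
    out$strand <- strand
  }
  out
}

#' Interval midpoints
#'
#' @param intervals Interval tibble (see [genomic_intervals()]).
#' @return Integer vector `floor((start + end) / 2)`.
#' @export
interval_midpoint <- function(intervals) {
  as.integer((as.numeric(intervals$start) + as.numeric(intervals$end)) %/% 2)
}

# 0-based half-open tibble -> 1-based closed GRanges (internal)
.gi_as_granges <- function(intervals) {
  GenomicRanges::GRanges(
    seqnames = intervals$chrom,
    ranges = IRanges::IRanges(start = intervals$start + 1L,
                              end = intervals$end)
  )
}

#' Fraction of query intervals overlapping a subject set
#'
#' Computes the fraction of query intervals that overlap at least one
#' subject interval by >= 1 bp, e.g. the fraction of open-chromatin peaks
#' that coincide with histone-mark peaks.
#'
#' @param query,subject Interval tibbles.
#' @return A single number in `[0, 1]`.
#' @export
overlap_fraction <- function(query, subject) {
  if (is.null(query) || nrow(query) == 0L) {
    stop("query interval set is empty")
  }
  if (is.null(subject) || nrow(subject) == 0L) {
    stop("subject interval set is empty")
  }
  hits <- suppressWarnings(
    GenomicRanges::countOverlaps(.gi_as_granges(query),
                                 .gi_as_granges(subject))
  )
  mean(hits > 0L)
}

#' Construct a gene model set
#'
#' @param genes Tibble with columns `gene_id` (unique), `chrom`, `start`,
#'   `end` (gene span, 0-based half-open), `strand` (`"+"`/`"-"`). The TSS is
#'   derived as `start` for `+` genes and `end - 1` for `-` genes.
#' @param exons Optional tibble with columns `gene_id`, `chrom`, `start`,
#'   `end`; exons of a gene must be non-overlapping. Defaults to one exon
#'   spanning each gene.
#'
#' @return An object of class `gene_models`: a list with elements `genes`
#'   (with an added `tss` column) and `exons`.
#' @export
gene_models <- function(genes, exons = NULL) {
  stopifnot(all(c("gene_id", "chrom", "start", "end", "strand") %in%
                  names(genes)))
  if (anyDuplicated(genes$gene_id)) stop("gene_id values must be unique")
  if (!all(genes$strand %in% c("+", "-"))) {
    stop("gene strand must be '+' or '-'")
  }
  if (any(genes$start >= genes$end)) stop("gene spans must satisfy start < end")
  genes <- tibble::as_tibble(genes)
  genes$tss <- ifelse(genes$strand == "+", genes$start, genes$end - 1L)
  genes$tss <- as.integer(genes$tss)
  if (is.null(exons)) {
    exons <- tibble::tibble(gene_id = genes$gene_id, chrom = genes$chrom,
                            start = genes$start, end = genes$end)
  } else {
    stopifnot(all(c("gene_id", "chrom", "start", "end") %in% names(exons)))
    exons <- tibble::as_tibble(exons)
    exons <- exons[order(exons$gene_id, exons$start), ]
    split_starts <- split(exons$start, exons$gene_id)
    split_ends <- split(exons$end, exons$gene_id)
    for (g in names(split_starts)) {
      s <- split_starts[[g]]; e <- split_ends[[g]]
      if (length(s) > 1L && any(s[-1L] < e[-length(e)])) {
        stop("exons of gene '", g, "' overlap")
      }
    }
  }
  structure(list(genes = genes, exons = exons), class = "gene_models")
}

#' @export
print.gene_models <- function(x, ...) {
  cat("gene_models:", nrow(x$genes), "genes,", nrow(x$exons), "exons\n")
  invisible(x)
}

#' Annotate loci with a genomic feature label
#'
#' Each locus midpoint receives exactly one label among `promoter`, `exon`,
#' `intron`, `intergenic`, resolved with fixed priority
#' promoter > exon > intron > intergenic. The promoter window is strand-aware
#' relative to the TSS: for a `+` gene with window `c(-1000, 100)` it spans
#' `[tss - 1000, tss + 100]`.
#'
#' @param loci Interval tibble.
#' @param genes A [gene_models()] object.
#' @param promoter_window Length-2 numeric, bp offsets (upstream negative,
#'   downstream positive) around the TSS.
#' @return Character vector of feature labels, one per locus.
#' @export
annotate_locus <- function(loci, genes, promoter_window = c(-1000, 100)) {
  stopifnot(inherits(genes, "gene_models"), length(promoter_window) == 2L)
  mid <- interval_midpoint(loci)
  gtab <- genes$genes
  missing_chrom <- !(loci$chrom %in% gtab$chrom)
  if (any(missing_chrom)) {
    warning(sum(missing_chrom),
            " locus/loci on chromosomes absent from the annotation; ",
            "labelled intergenic")
  }
  pts <- GenomicRanges::GRanges(loci$chrom,
                                IRanges::IRanges(mid + 1L, mid + 1L))
  # promoter ranges, strand-aware
  up <- promoter_window[1]; down <- promoter_window[2]
  prom_start <- ifelse(gtab$strand == "+", gtab$tss + up, gtab$tss - down)
  prom_end <- ifelse(gtab$strand == "+", gtab$tss + down, gtab$tss - up)
  prom <- GenomicRanges::GRanges(
    gtab$chrom,
    IRanges::IRanges(pmax(prom_start, 0) + 1L, pmax(prom_end + 1L, 1L))
  )
  exon_gr <- GenomicRanges::GRanges(
    genes$exons$chrom,
    IRanges::IRanges(genes$exons$start + 1L, genes$exons$end)
  )
  span_gr <- GenomicRanges::GRanges(
    gtab$chrom, IRanges::IRanges(gtab$start + 1L, gtab$end)
  )
  in_prom <- suppressWarnings(GenomicRanges::countOverlaps(pts, prom)) > 0L
  in_exon <- suppressWarnings(GenomicRanges::countOverlaps(pts, exon_gr)) > 0L
  in_span <- suppressWarnings(GenomicRanges::countOverlaps(pts, span_gr)) > 0L
  labels <- rep("intergenic", nrow(loci))
  labels[in_span] <- "intron"
  labels[in_exon] <- "exon"
  labels[in_prom] <- "promoter"
  labels
}
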