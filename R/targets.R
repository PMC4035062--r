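#' Partition nearby genes into exclusive neighbourhoods of two locus sets
#'
#' Genes within `window` of loci from both sets ("overlapped") are excluded
#' from target assignment, since clustered enhancers of the two cell types
#' would otherwise claim the same genes.
#'
#' @param set_a_loci,set_b_loci Interval tibbles (non-empty).
#' @param genes A [gene_models()] object.
#' @param window Window half-width in bp.
#' @return List with character vectors `genes_a_only`, `genes_b_only`,
#'   `overlapped`.
#' @export
exclusive_nearby_genes <- function(set_a_loci, set_b_loci, genes,
                                   window = 100e3) {
  if (nrow(set_a_loci) == 0L || nrow(set_b_loci) == 0L) {
    stop("both locus sets must be non-empty")
  }
  near_a <- genes_within_window(set_a_loci, genes, window)$gene_id
  near_b <- genes_within_window(set_b_loci, genes, window)$gene_id
  list(genes_a_only = setdiff(near_a, near_b),
       genes_b_only = setdiff(near_b, near_a),
       overlapped = intersect(near_a, near_b))
}

#' Assign putative target genes to active enhancers
#'
#' One assignment per (active enhancer, gene) pair with TSS-to-midpoint
#' distance strictly below `window`, where the gene is concordantly
#' overexpressed in the enhancer's cell type (adjusted p < 0.05 and fold
#' change in the matching direction). Many-to-many links are allowed: one
#' enhancer may regulate several genes and one gene may be claimed by
#' several enhancers.
#'
#' @param active_loci Interval tibble of active enhancers; if a `state`
#'   column is present all values must be `"active"`.
#' @param exclusive_genes Character vector of candidate gene ids (typically
#'   one side of [exclusive_nearby_genes()]).
#' @param genes A [gene_models()] object (source of TSS positions).
#' @param expression Expression tibble.
#' @param direction `"a"` if the enhancers are A-specific (targets must be
#'   over_A), `"b"` otherwise.
#' @param window Window half-width in bp.
#' @return Tibble with columns `enhancer`, `gene_id`, `distance`,
#'   `concordant` (all `TRUE` by construction).
#' @export
assign_targets <- function(active_loci, exclusive_genes, genes, expression,
                           direction = c("a", "b"), window = 100e3) {
  direction <- match.arg(direction)
  stopifnot(inherits(genes, "gene_models"))
  if ("state" %in% names(active_loci) &&
      any(active_loci$state != "active")) {
    stop("non-active locus supplied to assign_targets")
  }
  cat <- categorize_genes(expression)
  want <- if (direction == "a") "over_A" else "over_B"
  keep <- exclusive_genes[!is.na(cat[exclusive_genes]) &
                            cat[exclusive_genes] == want]
  g <- genes$genes[genes$genes$gene_id %in% keep, ]
  empty <- tibble::tibble(enhancer = character(), gene_id = character(),
                          distance = numeric(), concordant = logical())
  if (nrow(g) == 0L || nrow(active_loci) == 0L) return(empty)
  mid <- interval_midpoint(active_loci)
  enh_name <- if ("name" %in% names(active_loci)) active_loci$name else
    paste0(active_loci$chrom, ":", active_loci$start, "-", active_loci$end)
  rows <- list()
  for (chr in unique(active_loci$chrom)) {
    esel <- which(active_loci$chrom == chr)
    gsel <- which(g$chrom == chr)
    if (!length(gsel)) next
    ord <- order(g$tss[gsel])
    tss <- g$tss[gsel][ord]
    ids <- g$gene_id[gsel][ord]
    for (i in esel) {
      lo <- findInterval(mid[i] - window, tss) + 1L
      hi <- findInterval(mid[i] + window - 0.5, tss)
      if (hi < lo) next
      d <- abs(tss[lo:hi] - mid[i])
      in_win <- d < window
      if (!any(in_win)) next
      rows[[length(rows) + 1L]] <- tibble::tibble(
        enhancer = enh_name[i], gene_id = ids[lo:hi][in_win],
        distance = d[in_win], concordant = TRUE
      )
    }
  }
  if (!length(rows)) return(empty)
  do.call(rbind, rows)
}

#' Multiplicity of enhancer-target links
#'
#' @param assignments Output of [assign_targets()].
#' @return List with `max_genes_per_enhancer`, `max_enhancers_per_gene`,
#'   and the full degree histograms `genes_per_enhancer`,
#'   `enhancers_per_gene` (named integer tables). All zeros when
#'   `assignments` is empty.
#' @export
multiplicity_summary <- function(assignments) {
  if (nrow(assignments) == 0L) {
    return(list(max_genes_per_enhancer = 0L, max_enhancers_per_gene = 0L,
                genes_per_enhancer = table(integer(0)),
                enhancers_per_gene = table(integer(0))))
  }
  per_enh <- table(assignments$enhancer)
  per_gene <- table(assignments$gene_id)
  list(max_genes_per_enhancer = as.integer(max(per_enh)),
       max_enhancers_per_gene = as.integer(max(per_gene)),
       genes_per_enhancer = table(as.integer(per_enh)),
       enhancers_per_gene = table(as.integer(per_gene)))
}

#' Per-term enrichment between two gene sets
#'
#' For each term annotating at least one gene of either set, tests the 2x2
#' table `[in_a, |A| - in_a; in_b, |B| - in_b]` with [chi_square_2x2()],
#' keeps terms with p below `alpha`, and reports `-log2(p)` (the published
#' bar-plot scale for ontology comparisons).
#'
#' @param genes_a,genes_b Character vectors of gene ids (e.g. target genes
#'   of the two cell types' active enhancers).
#' @param term_map Tibble with columns `gene_id`, `term_id`.
#' @param alpha Per-term significance cutoff.
#' @return Tibble with columns `term_id`, `count_a`, `count_b`, `total_a`,
#'   `total_b`, `p_value`, `neg_log2_p`, sorted ascending p.
#' @export
category_enrichment <- function(genes_a, genes_b, term_map, alpha = 0.05) {
  total_a <- length(unique(genes_a))
  total_b <- length(unique(genes_b))
  if (total_a == 0L || total_b == 0L) stop("both gene sets must be non-empty")
  tm <- unique(term_map[term_map$gene_id %in% c(genes_a, genes_b), ])
  terms <- unique(tm$term_id)
  rows <- lapply(terms, function(t) {
    members <- tm$gene_id[tm$term_id == t]
    ca <- length(intersect(members, genes_a))
    cb <- length(intersect(members, genes_b))
    if (ca + cb == 0L) return(NULL)  # term with no members in either set
    if ((total_a - ca) + (total_b - cb) == 0L) return(NULL)
    ct <- chi_square_2x2(ca, total_a - ca, cb, total_b - cb)
    tibble::tibble(term_id = t, count_a = ca, count_b = cb,
                   total_a = total_a, total_b = total_b,
                   p_value = ct$p_value, neg_log2_p = -log2(ct$p_value))
  })
  rows <- rows[!vapply(rows, is.null, TRUE)]
  if (!length(rows)) {
    return(tibble::tibble(term_id = character(), count_a = integer(),
                          count_b = integer(), total_a = integer(),
                          total_b = integer(), p_value = numeric(),
                          neg_log2_p = numeric()))
  }
  out <- do.call(rbind, rows)
  out <- out[out$p_value < alpha, ]
  out[order(out$p_value, out$term_id), ]
}
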