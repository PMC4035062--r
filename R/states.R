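#' Build a binned signal matrix around locus midpoints
#'
#' Rows are loci, columns are fixed-width bins spanning
#' `[midpoint - window, midpoint + window)`; entries are tag counts
#' normalized to tags per 1e7. The underlying data of density heatmaps and
#' mean-profile ("metaplot") figures.
#'
#' @param track A [tag_track()].
#' @param loci Interval tibble; row names of the matrix are taken from the
#'   `name` column when present.
#' @param window Half-window in bp; must be a multiple of `bin_size`.
#' @param bin_size Bin width in bp.
#' @return Numeric matrix, loci x (2 * window / bin_size) bins.
#' @export
build_signal_matrix <- function(track, loci, window = 5000, bin_size = 100) {
  stopifnot(inherits(track, "tag_track"))
  if (window %% bin_size != 0) {
    stop("window must be a multiple of bin_size")
  }
  n_bins <- as.integer(2 * window / bin_size)
  mid <- interval_midpoint(loci)
  m <- matrix(0, nrow = nrow(loci), ncol = n_bins)
  for (chr in unique(loci$chrom)) {
    sel <- which(loci$chrom == chr)
    pos <- track$positions[[chr]]
    if (is.null(pos) || length(pos) == 0L) next
    for (i in sel) {
      lo <- mid[i] - window
      a <- findInterval(lo - 0.5, pos)
      b <- findInterval(mid[i] + window - 0.5, pos)
      if (b <= a) next
      bins <- (pos[(a + 1L):b] - lo) %/% bin_size + 1L
      tb <- tabulate(bins, nbins = n_bins)
      m[i, ] <- tb
    }
  }
  m <- m / track$library_size * 1e7
  if ("name" %in% names(loci)) rownames(m) <- loci$name
  m
}

#' Mean signal profile across loci
#'
#' @param matrix A signal matrix from [build_signal_matrix()].
#' @return Numeric vector of column means (per-bin mean density).
#' @export
mean_profile <- function(matrix) {
  if (is.null(dim(matrix)) || nrow(matrix) == 0L) {
    stop("signal matrix has no loci")
  }
  colMeans(matrix)
}

# Exact 1-D 2-means: minimize total within-cluster sum of squares over all
# contiguous splits of the sorted values (for k = 2 in one dimension the
# optimal clusters are intervals, so the split scan finds the global
# optimum). Returns the assignment in input order, 1 = lower cluster.
.two_means_1d <- function(x) {
  n <- length(x)
  ord <- order(x)
  s <- x[ord]
  if (s[1] == s[n]) stop("degenerate clustering: all features identical")
  cs <- cumsum(s)
  cs2 <- cumsum(s^2)
  k <- seq_len(n - 1L)
  ss_left <- cs2[k] - cs[k]^2 / k
  ss_right <- (cs2[n] - cs2[k]) - (cs[n] - cs[k])^2 / (n - k)
  best <- which.min(ss_left + ss_right)
  assign_sorted <- rep(2L, n)
  assign_sorted[seq_len(best)] <- 1L
  out <- integer(n)
  out[ord] <- assign_sorted
  out
}

#' Classify enhancer loci as poised or active
#'
#' The per-locus feature is the normalized H3K27Ac tag count in a
#' +/- `flank` bp window around the midpoint. Loci are partitioned by exact
#' one-dimensional 2-means (globally optimal contiguous split of the sorted
#' features, deterministic); the cluster with the higher mean feature is
#' labelled `active`, the other `poised`.
#'
#' @param loci Interval tibble (a `name` column is carried through as
#'   `locus`).
#' @param k27_track H3K27Ac [tag_track()] for the matching cell type.
#' @param flank Half-window in bp for the density feature.
#' @return Tibble with columns `locus`, `state` (`"poised"`/`"active"`),
#'   `k27_feature`.
#' @export
classify_poised_active <- function(loci, k27_track, flank = 1000) {
  if (nrow(loci) < 2L) stop("need at least 2 loci to cluster")
  feature <- normalize_counts(count_tags(k27_track, loci, flank),
                              k27_track$library_size)
  cl <- .two_means_1d(feature)
  m1 <- mean(feature[cl == 1L])
  m2 <- mean(feature[cl == 2L])
  active_cluster <- if (m2 > m1) 2L else 1L
  tibble::tibble(
    locus = if ("name" %in% names(loci)) loci$name else
      paste0(loci$chrom, ":", loci$start, "-", loci$end),
    state = ifelse(cl == active_cluster, "active", "poised"),
    k27_feature = feature
  )
}

#' Flag nucleosome-depleted loci by FAIRE peak intersection
#'
#' A locus is flagged when its midpoint +/- `flank` bp window overlaps any
#' FAIRE peak by >= 1 bp.
#'
#' @param loci Interval tibble.
#' @param faire_peaks FAIRE peak interval tibble.
#' @param flank Slop in bp around the locus midpoint.
#' @return Logical vector, one flag per locus.
#' @export
faire_flag <- function(loci, faire_peaks, flank = 500) {
  if (is.null(faire_peaks) || nrow(faire_peaks) == 0L) {
    return(rep(FALSE, nrow(loci)))
  }
  mid <- interval_midpoint(loci)
  win <- tibble::tibble(chrom = loci$chrom,
                        start = pmax(mid - flank, 0L),
                        end = mid + flank)
  suppressWarnings(
    GenomicRanges::countOverlaps(.gi_as_granges(win),
                                 .gi_as_granges(faire_peaks))
  ) > 0L
}
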