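#' Construct a tag track
#'
#' A tag track holds the mapped positions of sequencing tags (one genomic
#' position per tag, e.g. the 5' end of each aligned read) for one
#' mark/sample, plus the library size used for depth normalization
#' (tags per 1e7).
#'
#' @param positions Named list, one sorted integer vector of tag positions
#'   per chromosome. Unsorted vectors are sorted on construction.
#' @param library_size Total number of tags in the library; defaults to the
#'   number of stored positions. Must be >= that number.
#' @return An object of class `tag_track`.
#' @export
tag_track <- function(positions, library_size = NULL) {
  stopifnot(is.list(positions), !is.null(names(positions)))
  positions <- lapply(positions, function(p) sort(as.numeric(p)))
  n <- sum(vapply(positions, length, 1L))
  if (is.null(library_size)) library_size <- n
  if (library_size < n) {
    stop("library_size (", library_size, ") smaller than stored tag count (",
         n, ")")
  }
  if (library_size <= 0) stop("library_size must be positive")
  structure(list(positions = positions, library_size = library_size),
            class = "tag_track")
}

#' @export
print.tag_track <- function(x, ...) {
  cat("tag_track:", sum(vapply(x$positions, length, 1L)), "tags on",
      length(x$positions), "chromosome(s); library size", x$library_size, "\n")
  invisible(x)
}

#' Count tags around locus midpoints
#'
#' Counts tag positions falling in `[midpoint - flank, midpoint + flank)`
#' for each locus, by binary search on the sorted per-chromosome positions.
#'
#' @param track A [tag_track()].
#' @param loci Interval tibble.
#' @param flank Half-window in bp (> 0).
#' @return Integer vector of counts, one per locus.
#' @export
count_tags <- function(track, loci, flank = 500) {
  stopifnot(inherits(track, "tag_track"))
  if (flank <= 0) stop("flank must be positive")
  mid <- interval_midpoint(loci)
  counts <- integer(nrow(loci))
  for (chr in unique(loci$chrom)) {
    sel <- which(loci$chrom == chr)
    pos <- track$positions[[chr]]
    if (is.null(pos) || length(pos) == 0L) next
    lo <- findInterval(mid[sel] - flank - 0.5, pos)
    hi <- findInterval(mid[sel] + flank - 0.5, pos)
    counts[sel] <- hi - lo
  }
  counts
}

#' Normalize raw tag counts to tags per 1e7
#'
#' @param counts Raw counts.
#' @param library_size Library size of the originating track.
#' @return Numeric vector `counts / library_size * 1e7`.
#' @export
normalize_counts <- function(counts, library_size) {
  if (library_size <= 0) stop("library_size must be positive")
  counts / library_size * 1e7
}
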