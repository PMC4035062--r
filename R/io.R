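#' Read a BED3+ file
#'
#' Parses tab-separated BED with 3-6 columns (chrom, start, end, name,
#' score, strand). Coordinates are kept in the native BED convention
#' (0-based, half-open). Malformed coordinates are reported with their line
#' number.
#'
#' @param path Path to a BED file.
#' @return An interval tibble (see [genomic_intervals()]).
#' @export
read_bed <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  if (length(lines) == 0L) stop("empty BED file: ", path)
  fields <- strsplit(lines, "\t", fixed = TRUE)
  nf <- lengths(fields)
  if (any(nf < 3L)) {
    stop("BED parse error at line ", which(nf < 3L)[1], ": fewer than 3 fields")
  }
  chrom <- vapply(fields, `[[`, "", 1L)
  start_chr <- vapply(fields, `[[`, "", 2L)
  end_chr <- vapply(fields, `[[`, "", 3L)
  start <- suppressWarnings(as.integer(start_chr))
  end <- suppressWarnings(as.integer(end_chr))
  bad <- which(is.na(start) | is.na(end) |
                 start_chr != as.character(start) |
                 end_chr != as.character(end))
  if (length(bad)) {
    stop("BED parse error at line ", bad[1], ": non-integer coordinates")
  }
  bad <- which(start >= end)
  if (length(bad)) {
    stop("BED parse error at line ", bad[1], ": start >= end")
  }
  out <- tibble::tibble(chrom = chrom, start = start, end = end)
  if (all(nf >= 4L)) out$name <- vapply(fields, `[[`, "", 4L)
  if (all(nf >= 5L)) {
    out$score <- suppressWarnings(as.numeric(vapply(fields, `[[`, "", 5L)))
  }
  if (all(nf >= 6L)) out$strand <- vapply(fields, `[[`, "", 6L)
  out
}

#' Write intervals to a BED file
#'
#' Emits sorted (chrom, start, end) tab-separated output; optional name,
#' score and strand columns are written when present so that
#' `read_bed(write_bed(x))` round-trips losslessly.
#'
#' @param intervals Interval tibble.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_bed <- function(intervals, path) {
  ord <- order(intervals$chrom, intervals$start, intervals$end)
  x <- intervals[ord, ]
  cols <- list(x$chrom, x$start, x$end)
  for (nm in c("name", "score", "strand")) {
    if (!is.null(x[[nm]])) cols <- c(cols, list(x[[nm]])) else break
  }
  lines <- do.call(paste, c(cols, sep = "\t"))
  writeLines(lines, path)
  invisible(path)
}

#' Read position frequency matrices in JASPAR text format
#'
#' Accepts the JASPAR 2016+ bracketed format:
#' ```
#' >MA0000.1 NAME
#' A [ 4 19 0 ... ]
#' C [ ... ]
#' ```
#' as well as plain 4-row count blocks after each header.
#'
#' @param path Path to the motif file.
#' @param database Database tag attached to every motif (e.g. `"JASPAR"`).
#' @return A named list of PFMs; each PFM is a 4 x w numeric matrix with
#'   rownames `A`, `C`, `G`, `T` and attributes `name` and `database`.
#' @export
read_jaspar_pfm <- function(path, database = "JASPAR") {
  lines <- trimws(readLines(path))
  lines <- lines[nzchar(lines)]
  headers <- grep("^>", lines)
  if (!length(headers)) stop("no motif headers ('>') found in ", path)
  ends <- c(headers[-1L] - 1L, length(lines))
  motifs <- list()
  for (i in seq_along(headers)) {
    header <- sub("^>\\s*", "", lines[headers[i]])
    toks <- strsplit(header, "\\s+")[[1]]
    name <- if (length(toks) >= 2L) toks[2L] else toks[1L]
    block <- lines[(headers[i] + 1L):ends[i]]
    if (length(block) < 4L) stop("motif '", name, "': expected 4 count rows")
    rows <- lapply(block[1:4], function(l) {
      l <- sub("^[ACGTacgt]\\s*", "", l)
      l <- gsub("[\\[\\]]", "", l, perl = TRUE)
      as.numeric(strsplit(trimws(l), "\\s+")[[1]])
    })
    w <- unique(lengths(rows))
    if (length(w) != 1L) stop("motif '", name, "': ragged count rows")
    pfm <- do.call(rbind, rows)
    rownames(pfm) <- c("A", "C", "G", "T")
    if (any(pfm < 0) || any(colSums(pfm) <= 0)) {
      stop("motif '", name, "': invalid counts")
    }
    attr(pfm, "name") <- name
    attr(pfm, "database") <- database
    motifs[[name]] <- pfm
  }
  motifs
}

#' Read a minimal MEME-format motif file
#'
#' Parses `MOTIF` blocks with `letter-probability matrix` sections (the
#' minimal MEME text format). Probabilities are rescaled to pseudo-counts
#' using the stated `nsites` (default 20).
#'
#' @param path Path to a MEME text file.
#' @param database Database tag attached to every motif.
#' @return A named list of PFMs as in [read_jaspar_pfm()].
#' @export
read_meme_pfm <- function(path, database = "MEME") {
  lines <- readLines(path)
  idx <- grep("^MOTIF", lines)
  if (!length(idx)) stop("no MOTIF blocks found in ", path)
  motifs <- list()
  for (i in idx) {
    toks <- strsplit(trimws(lines[i]), "\\s+")[[1]]
    name <- toks[2L]
    j <- i + 1L
    while (j <= length(lines) &&
           !grepl("^letter-probability matrix", lines[j])) j <- j + 1L
    if (j > length(lines)) stop("motif '", name, "': no probability matrix")
    hdr <- lines[j]
    w <- as.integer(sub(".*w=\\s*(\\d+).*", "\\1", hdr))
    nsites <- if (grepl("nsites=", hdr)) {
      as.numeric(sub(".*nsites=\\s*([0-9.]+).*", "\\1", hdr))
    } else 20
    probs <- t(vapply(lines[(j + 1L):(j + w)], function(l) {
      as.numeric(strsplit(trimws(l), "\\s+")[[1]])
    }, numeric(4), USE.NAMES = FALSE))
    pfm <- t(probs) * nsites
    rownames(pfm) <- c("A", "C", "G", "T")
    attr(pfm, "name") <- name
    attr(pfm, "database") <- database
    motifs[[name]] <- pfm
  }
  motifs
}

#' Read region sequences from FASTA
#'
#' @param path Path to an (uncompressed) FASTA file.
#' @return Named character vector of upper-case sequences.
#' @export
read_region_fasta <- function(path) {
  x <- Biostrings::readDNAStringSet(path)
  stats::setNames(toupper(as.character(x)), names(x))
}

#' Write region sequences to FASTA
#'
#' @param sequences Named character vector of sequences.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_region_fasta <- function(sequences, path) {
  Biostrings::writeXStringSet(Biostrings::DNAStringSet(sequences), path)
  invisible(path)
}

#' Write a tab-separated table with header
#'
#' @param x Data frame.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_tsv_table <- function(x, path) {
  utils::write.table(x, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a tab-separated table with header
#'
#' @param path Input path.
#' @return A tibble.
#' @export
read_tsv_table <- function(path) {
  tibble::as_tibble(utils::read.delim(path, sep = "\t",
                                      stringsAsFactors = FALSE))
}
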