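#' Convert a position frequency matrix to a log-odds weight matrix
#'
#' `score(b, i) = log2(((count(b, i) + pseudocount * bg_b) /
#' (colsum_i + pseudocount)) / bg_b)`.
#'
#' @param pfm 4 x w count matrix with rownames `A`, `C`, `G`, `T` (as read
#'   by [read_jaspar_pfm()]).
#' @param background Length-4 base frequencies summing to 1 (names
#'   `A`, `C`, `G`, `T`); default uniform.
#' @param pseudocount Total pseudocount spread over the bases by their
#'   background frequency.
#' @return Object of class `pwm`: list with `scores` (4 x w log2-odds
#'   matrix), `background`, `pseudocount`, `name`, `database`.
#' @export
pfm_to_pwm <- function(pfm, background = c(A = 0.25, C = 0.25,
                                           G = 0.25, T = 0.25),
                       pseudocount = 0.1) {
  stopifnot(nrow(pfm) == 4L)
  motif_name <- attr(pfm, "name")
  motif_db <- attr(pfm, "database")
  if (is.null(rownames(pfm))) rownames(pfm) <- c("A", "C", "G", "T")
  pfm <- pfm[c("A", "C", "G", "T"), , drop = FALSE]
  background <- background[c("A", "C", "G", "T")]
  if (abs(sum(background) - 1) > 1e-6) {
    stop("background frequencies must sum to 1")
  }
  colsum <- colSums(pfm)
  if (any(colsum <= 0)) stop("PFM has a zero column")
  probs <- sweep(pfm + outer(background, rep(pseudocount, ncol(pfm))),
                 2, colsum + pseudocount, "/")
  scores <- log2(probs / background)
  structure(list(scores = scores, background = background,
                 pseudocount = pseudocount,
                 name = motif_name, database = motif_db),
            class = "pwm")
}

#' @export
print.pwm <- function(x, ...) {
  cat("pwm:", if (!is.null(x$name)) x$name else "<unnamed>",
      "width", ncol(x$scores), "\n")
  invisible(x)
}

# Exact distribution of the (discretized) match score under the background
# model: dynamic programme convolving per-column score distributions.
# Scores are rounded to multiples of eps; returns integer support (in eps
# units) and probability masses.
.score_distribution <- function(pwm, eps = 0.01) {
  s_int <- round(pwm$scores / eps)
  w <- ncol(s_int)
  lo_tot <- sum(apply(s_int, 2, min))
  hi_tot <- sum(apply(s_int, 2, max))
  size <- hi_tot - lo_tot + 1L
  mass <- numeric(size)  # index i <-> score lo_tot + i - 1
  mass[1L] <- 1
  lo_cur <- 0L
  for (j in seq_len(w)) {
    new_lo <- lo_cur + min(s_int[, j])
    new_mass <- numeric(size)
    for (b in 1:4) {
      shift <- s_int[b, j] - min(s_int[, j])
      p <- pwm$background[b]
      if (shift == 0L) {
        new_mass <- new_mass + p * mass
      } else {
        new_mass[(shift + 1L):size] <- new_mass[(shift + 1L):size] +
          p * mass[1:(size - shift)]
      }
    }
    mass <- new_mass
    lo_cur <- new_lo
  }
  keep <- mass > 0
  list(score_int = (lo_tot + seq_len(size) - 1L)[keep],
       mass = mass[keep], eps = eps)
}

#' Score threshold for a target p-value
#'
#' Computes the exact distribution of the motif match score under the
#' 0-order background model by dynamic programming over the discretized
#' per-column score distributions, then returns the smallest achievable
#' score whose upper-tail probability is <= `p` (the FIMO-style output
#' threshold, default p = 1e-4).
#'
#' @param pwm A [pfm_to_pwm()] object.
#' @param p Target upper-tail probability in (0, 1).
#' @param eps Discretization step in log2-odds units.
#' @return Score threshold (log2-odds). If no achievable score has tail
#'   <= `p`, the maximum achievable score is returned with a warning.
#' @export
score_threshold <- function(pwm, p = 1e-4, eps = 0.01) {
  stopifnot(inherits(pwm, "pwm"))
  if (p <= 0 || p >= 1) stop("p must be in (0, 1)")
  dist <- .score_distribution(pwm, eps)
  tail <- rev(cumsum(rev(dist$mass)))
  ok <- which(tail <= p + 1e-12)
  if (!length(ok)) {
    warning("no achievable score has tail probability <= ", p,
            "; returning the maximum score")
    return(max(dist$score_int) * eps)
  }
  dist$score_int[ok[1]] * eps
}

# encode A/C/G/T -> 1..4, anything else NA
.encode_seq <- function(seq) {
  code <- c(A = 1L, C = 2L, G = 3L, T = 4L)
  unname(code[strsplit(toupper(seq), "")[[1]]])
}

# score all windows of an encoded sequence against an integer-coded score
# matrix; windows containing NA (e.g. N bases) score -Inf
.score_windows <- function(enc, scores) {
  w <- ncol(scores)
  n <- length(enc) - w + 1L
  if (n < 1L) return(numeric(0))
  total <- numeric(n)
  for (j in seq_len(w)) {
    col <- scores[, j][enc[j:(j + n - 1L)]]
    total <- total + col
  }
  total[is.na(total)] <- -Inf
  total
}

#' Scan region sequences for motif matches
#'
#' Scans both strands (the reverse strand via the reverse-complemented
#' matrix) and calls a window a hit when its rounded score reaches the
#' threshold. Windows containing `N` are skipped; regions shorter than the
#' motif are reported unhit with a warning.
#'
#' @param sequences Named character vector of region sequences over
#'   `A`, `C`, `G`, `T`, `N`.
#' @param pwm A [pfm_to_pwm()] object.
#' @param threshold Score threshold from [score_threshold()].
#' @param eps Discretization step; must match the one used for the
#'   threshold.
#' @return List with `region_hit` (named logical, >= 1 hit per region) and
#'   `hits` (tibble `region`, `start` (1-based offset), `strand`, `score`).
#' @export
scan_regions <- function(sequences, pwm, threshold, eps = 0.01) {
  stopifnot(inherits(pwm, "pwm"))
  if (is.null(names(sequences))) {
    names(sequences) <- sprintf("region_%04d", seq_along(sequences))
  }
  s_int <- round(pwm$scores / eps)
  thr_int <- round(threshold / eps)
  w <- ncol(s_int)
  # reverse complement: reverse columns, swap A<->T and C<->G rows
  s_rc <- s_int[c(4L, 3L, 2L, 1L), rev(seq_len(w)), drop = FALSE]
  short <- nchar(sequences) < w
  if (any(short)) {
    warning(sum(short), " region(s) shorter than the motif; reported unhit")
  }
  hit <- stats::setNames(rep(FALSE, length(sequences)), names(sequences))
  rows <- list()
  for (i in which(!short)) {
    enc <- .encode_seq(sequences[[i]])
    for (str in c("+", "-")) {
      sc <- .score_windows(enc, if (str == "+") s_int else s_rc)
      pos <- which(sc >= thr_int)
      if (length(pos)) {
        hit[i] <- TRUE
        rows[[length(rows) + 1L]] <- tibble::tibble(
          region = names(sequences)[i], start = pos, strand = str,
          score = sc[pos] * eps
        )
      }
    }
  }
  hits <- if (length(rows)) do.call(rbind, rows) else {
    tibble::tibble(region = character(), start = integer(),
                   strand = character(), score = numeric())
  }
  list(region_hit = hit, hits = hits)
}

#' Motif enrichment table between two region sets
#'
#' For each motif, tests the 2x2 table
#' `[count_a, total_a - count_a; count_b, total_b - count_b]` with
#' [chi_square_2x2()] (counts are regions containing >= 1 hit), keeps rows
#' with p below `alpha`, and sorts ascending by p — the layout of a
#' published motif-enrichment table (name, count in set A, count in set B,
#' p-value, database). A BH-adjusted column is added for reference; the
#' `alpha` filter itself is applied to the unadjusted p.
#'
#' @param hits_a,hits_b Named integer vectors (motif -> number of hit
#'   regions) for the two sets.
#' @param total_a,total_b Region totals per set (> 0).
#' @param motifs Named list of PFMs or PWMs (used for database tags);
#'   optional.
#' @param alpha Per-test significance cutoff.
#' @return Tibble with columns `motif`, `count_a`, `count_b`, `total_a`,
#'   `total_b`, `p_value`, `p_adj_bh`, `database`, sorted ascending p.
#' @export
enrichment_table <- function(hits_a, total_a, hits_b, total_b,
                             motifs = NULL, alpha = 0.05) {
  if (total_a <= 0 || total_b <= 0) stop("region totals must be positive")
  common <- union(names(hits_a), names(hits_b))
  if (is.null(common)) stop("hit vectors must be named by motif")
  ca <- stats::setNames(rep(0L, length(common)), common)
  cb <- ca
  ca[names(hits_a)] <- hits_a
  cb[names(hits_b)] <- hits_b
  if (any(ca > total_a) || any(cb > total_b)) {
    stop("hit counts exceed region totals")
  }
  db <- vapply(common, function(m) {
    obj <- motifs[[m]]
    d <- if (inherits(obj, "pwm")) obj$database else attr(obj, "database")
    if (is.null(d)) NA_character_ else d
  }, "")
  p <- vapply(common, function(m) {
    a <- ca[[m]]; b <- total_a - ca[[m]]
    c2 <- cb[[m]]; d2 <- total_b - cb[[m]]
    if ((a + c2) == 0L || (b + d2) == 0L) return(NA_real_)  # degenerate
    chi_square_2x2(a, b, c2, d2)$p_value
  }, 1)
  out <- tibble::tibble(motif = common, count_a = as.integer(ca),
                        count_b = as.integer(cb),
                        total_a = as.integer(total_a),
                        total_b = as.integer(total_b),
                        p_value = p,
                        p_adj_bh = stats::p.adjust(p, method = "BH"),
                        database = db)
  out <- out[!is.na(out$p_value) & out$p_value < alpha, ]
  out[order(out$p_value, out$motif), ]
}
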