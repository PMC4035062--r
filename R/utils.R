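# Minimal distance from each query point to a set of subject points,
# chromosome-aware. Returns Inf for queries on chromosomes with no subject
# point. Binary-search (findInterval) on sorted subject positions.
.nearest_distance <- function(query_chrom, query_pos, subj_chrom, subj_pos) {
  out <- rep(Inf, length(query_pos))
  subj_split <- split(subj_pos, subj_chrom)
  for (chr in names(subj_split)) {
    sel <- which(query_chrom == chr)
    if (!length(sel)) next
    sp <- sort(subj_split[[chr]])
    idx <- findInterval(query_pos[sel], sp)
    left <- ifelse(idx >= 1L, abs(query_pos[sel] - sp[pmax(idx, 1L)]), Inf)
    right <- ifelse(idx < length(sp),
                    abs(sp[pmin(idx + 1L, length(sp))] - query_pos[sel]), Inf)
    out[sel] <- pmin(left, right)
  }
  out
}

# Symmetric triangular jitter in [-half_width, half_width] (sum of two
# uniforms), mimicking a triangle-shaped tag pileup around a peak summit.
.triangular_offset <- function(n, half_width) {
  round(half_width * (stats::runif(n) + stats::runif(n) - 1))
}
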