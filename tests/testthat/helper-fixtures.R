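# Shared fixtures: a small seeded synthetic world (memoised per test run)
# and a consensus-based PFM builder.

small_config <- function(seed = 7, ...) {
  args <- list(
    chrom_sizes = c(chr1 = 3e7, chr2 = 3e7),
    n_genes = 400,
    n_specific_enhancers_per_type = 60,
    n_shared_enhancers = 60,
    tag_depth = 2e5,
    seed = seed
  )
  args[names(list(...))] <- list(...)
  do.call(synthetic_config, args)
}

.fixture_env <- new.env(parent = emptyenv())

small_dataset <- function() {
  if (is.null(.fixture_env$ds)) {
    .fixture_env$ds <- generate_dataset(small_config())
  }
  .fixture_env$ds
}

# PFM with `strength` counts on the consensus base, 1 elsewhere
consensus_pfm <- function(consensus, name = "motif_syn", database = "SYN",
                          strength = 17) {
  b <- strsplit(toupper(consensus), "")[[1]]
  pfm <- matrix(1, 4, length(b), dimnames = list(c("A", "C", "G", "T"), NULL))
  for (i in seq_along(b)) pfm[b[i], i] <- strength
  attr(pfm, "name") <- name
  attr(pfm, "database") <- database
  pfm
}

# truth lookups for the small dataset
truth_cell <- function(ds, names) ds$enhancers$cell[match(names, ds$enhancers$name)]
truth_state <- function(ds, names) ds$enhancers$state[match(names, ds$enhancers$name)]

loci_cols <- function(x) x[, c("chrom", "start", "end", "name")]
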