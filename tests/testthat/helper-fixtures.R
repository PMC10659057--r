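# Shared fixtures: random block generators, toy catalogs, a small simulation
# configuration. All randomness is seeded by the caller.

random_blocks <- function(n, queries = paste0("q", 1:4),
                          targets = paste0("t", 1:4)) {
  qlen <- sample(c(1000, 2999, 3000, 5000, 2e6), n, replace = TRUE)
  qs <- floor(runif(n, 0, qlen * 0.5))
  span <- pmax(1, floor(runif(n, 100, pmin(qlen - qs, 5e4))))
  blen <- pmax(span, floor(span * runif(n, 1, 1.2)))
  tlen <- pmax(blen * 4, 1e5)
  ts <- floor(runif(n, 0, tlen - blen))
  alignment_blocks(
    query_name = sample(queries, n, replace = TRUE),
    query_seq_len = qlen, query_start = qs, query_end = qs + span,
    strand = sample(c("+", "-"), n, replace = TRUE),
    target_name = sample(targets, n, replace = TRUE),
    target_seq_len = tlen, target_start = ts, target_end = ts + blen,
    residue_matches = floor(blen * runif(n, 0.5, 1)),
    block_len = blen,
    mapq = sample(0:60, n, replace = TRUE)
  )
}

# minimal block constructor for hand-built classifier scenarios
blk <- function(q, qs, qe, t, ts, te, strand = "+", qlen = 1e6,
                tlen = 1e6, mapq = 60) {
  alignment_blocks(
    query_name = q, query_seq_len = qlen, query_start = qs, query_end = qe,
    strand = strand, target_name = t, target_seq_len = tlen,
    target_start = ts, target_end = te,
    residue_matches = qe - qs, block_len = qe - qs, mapq = mapq
  )
}

toy_catalog <- function(names, lengths, chromosomes = names, x = NULL) {
  assembly_catalog(data.frame(
    name = names, length = lengths,
    status = ifelse(names %in% chromosomes, "chromosome", "unplaced_debris"),
    is_x = if (is.null(x)) FALSE else names == x,
    stringsAsFactors = FALSE
  ))
}

# compact simulation used by unit tests (the acceptance tests run the
# full-size default configuration)
small_sim_config <- function(seed = 1) {
  simulation_config(
    seed = seed,
    chromosome_lengths = c(chr1 = 6e5, chr2 = 5e5, chr3 = 4e5, chrX = 3e5),
    n_inversions = 3, n_translocations = 2, n_relocations = 2, n_debris = 2,
    inversion_size_bounds = c(2e3, 3e4),
    translocation_size_range = c(8e3, 2e4),
    relocation_size_range = c(8e3, 2e4),
    debris_size_range = c(1.5e4, 3e4),
    event_margin = 8e3
  )
}

# brute-force maximum-weight strictly-increasing-subsequence by enumeration
exhaustive_increasing_weight <- function(values, weights) {
  n <- length(values)
  best <- 0
  for (mask in seq_len(2^n) - 1) {
    idx <- which(bitwAnd(mask, 2^(seq_len(n) - 1)) > 0)
    if (length(idx) > 1 && any(diff(values[idx]) <= 0)) next
    best <- max(best, sum(weights[idx]))
  }
  best
}
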