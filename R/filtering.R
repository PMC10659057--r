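#' Alignment-block filter configuration
#'
#' Retention thresholds applied before discrepancy screening. A block is kept
#' only if its full query sequence length, alignment block length, mapping
#' quality and identity fraction all reach their thresholds; comparisons are
#' strict (`<` discards), so a block sitting exactly on a threshold is
#' retained. The defaults drop alignments too short or too ambiguous to
#' carry structural signal: query sequences under 3 kbp, blocks under 500 bp,
#' mapQ under 30 (about a 1/1000 mapping-error chance), and identity
#' (residue matches over block length) under 0.8. For comparisons involving
#' a highly fragmented assembly, `fragmented = TRUE` raises the query-length
#' floor to 1 Mbp so scaffolding noise from thousands of short sequences
#' does not masquerade as discrepancy.
#'
#' @param min_query_seq_len minimum full query sequence length, bp.
#' @param min_block_len minimum alignment block length, bp.
#' @param min_mapq minimum mapping quality.
#' @param min_match_fraction minimum residue_matches / block_len.
#' @param fragmented logical; apply the fragmented-genome query filter.
#' @param fragmented_min_query_seq_len query-length floor used when
#'   `fragmented` is `TRUE`.
#' @param stacked_overlap_fraction query-overlap fraction (of the shorter
#'   block) above which two blocks are considered stacked.
#' @return object of class `filter_config`.
#' @export
filter_config <- function(min_query_seq_len = 3000,
                          min_block_len = 500,
                          min_mapq = 30,
                          min_match_fraction = 0.8,
                          fragmented = FALSE,
                          fragmented_min_query_seq_len = 1e6,
                          stacked_overlap_fraction = 0.5) {
  stopifnot(
    min_query_seq_len >= 0, min_block_len >= 0, min_mapq >= 0,
    min_match_fraction >= 0, min_match_fraction <= 1,
    fragmented_min_query_seq_len >= 0,
    stacked_overlap_fraction >= 0, stacked_overlap_fraction <= 1
  )
  structure(
    list(
      min_query_seq_len = min_query_seq_len,
      min_block_len = min_block_len,
      min_mapq = min_mapq,
      min_match_fraction = min_match_fraction,
      fragmented = isTRUE(fragmented),
      fragmented_min_query_seq_len = fragmented_min_query_seq_len,
      stacked_overlap_fraction = stacked_overlap_fraction
    ),
    class = "filter_config"
  )
}

#' @keywords internal
filter_outcome <- function(retained, discarded, stacked) {
  structure(list(retained = retained, discarded = discarded,
                 stacked = stacked),
            class = "filter_outcome")
}

#' @export
print.filter_outcome <- function(x, ...) {
  cat(sprintf("Filter outcome: %d retained, %d discarded, %d stacked\n",
              nrow(x$retained), nrow(x$discarded), nrow(x$stacked)))
  if (nrow(x$discarded) > 0) {
    tab <- table(x$discarded$reason)
    cat("  discarded by reason:",
        paste(sprintf("%s=%d", names(tab), tab), collapse = ", "), "\n")
  }
  invisible(x)
}

#' Filter alignment blocks on length, quality and identity
#'
#' Partitions the input into retained and discarded blocks. A block is
#' discarded iff `query_seq_len < min_query_seq_len` (raised to the
#' fragmented floor when that mode is on), `block_len < min_block_len`,
#' `mapq < min_mapq`, or `residue_matches / block_len < min_match_fraction`.
#' Each discarded block carries the first failing reason, in that order.
#' Extra columns on the input table pass through untouched.
#'
#' @param blocks alignment-block table.
#' @param cfg a [filter_config()].
#' @return `filter_outcome` with `retained`, `discarded` (with a `reason`
#'   column), and an empty `stacked` slot (see [detect_stacked()]).
#' @export
filter_blocks <- function(blocks, cfg = filter_config()) {
  validate_blocks(blocks)
  min_qlen <- if (cfg$fragmented) {
    max(cfg$min_query_seq_len, cfg$fragmented_min_query_seq_len)
  } else {
    cfg$min_query_seq_len
  }
  reason <- rep(NA_character_, nrow(blocks))
  frac <- ifelse(blocks$block_len > 0,
                 blocks$residue_matches / blocks$block_len, 0)
  reason[is.na(reason) & frac < cfg$min_match_fraction] <- "low_match_fraction"
  reason[blocks$mapq < cfg$min_mapq] <- "low_mapq"
  reason[blocks$block_len < cfg$min_block_len] <- "block_too_short"
  reason[blocks$query_seq_len < min_qlen] <- "query_too_short"
  discarded <- blocks[!is.na(reason), , drop = FALSE]
  discarded$reason <- reason[!is.na(reason)]
  retained <- blocks[is.na(reason), , drop = FALSE]
  rownames(retained) <- rownames(discarded) <- NULL
  filter_outcome(retained, discarded, blocks[0, , drop = FALSE])
}

#' Query-interval overlap of two blocks as a fraction of the shorter
#' @keywords internal
overlap_fraction <- function(s1, e1, s2, e2) {
  ov <- pmax(0, pmin(e1, e2) - pmax(s1, s2))
  ov / pmin(e1 - s1, e2 - s2)
}

#' Set aside stacked alignment blocks
#'
#' Among retained blocks sharing a query sequence, whenever two query
#' intervals overlap by more than `stacked_overlap_fraction` of the shorter
#' block's span, the shorter block is set aside as "stacked" and takes no
#' part in classification (its bp count as unassessed). The rule is applied
#' repeatedly until no such pair remains among the kept blocks.
#' Deterministically, blocks are ranked by longer query span, then more
#' residue matches, then lexicographically smaller (target_name,
#' target_start), then smaller query_start; each block is kept unless it
#' over-overlaps an already-kept block, which makes the outcome independent
#' of input order.
#'
#' @param outcome a `filter_outcome` from [filter_blocks()], or an
#'   alignment-block table of already-retained blocks.
#' @param cfg a [filter_config()].
#' @return `filter_outcome` with stacked blocks moved out of `retained`.
#' @export
detect_stacked <- function(outcome, cfg = filter_config()) {
  if (is.data.frame(outcome)) {
    outcome <- filter_outcome(outcome, {
      d <- outcome[0, , drop = FALSE]
      d$reason <- character(0)
      d
    }, outcome[0, , drop = FALSE])
  }
  blocks <- outcome$retained
  if (nrow(blocks) < 2) return(outcome)
  frac <- cfg$stacked_overlap_fraction
  span <- query_span(blocks)
  ord <- order(blocks$query_name, -span, -blocks$residue_matches,
               blocks$target_name, blocks$target_start, blocks$query_start)
  stacked_idx <- logical(nrow(blocks))
  for (grp in split(ord, blocks$query_name[ord])) {
    kept <- integer(0)
    for (i in grp) {
      if (length(kept) > 0) {
        f <- overlap_fraction(blocks$query_start[i], blocks$query_end[i],
                              blocks$query_start[kept], blocks$query_end[kept])
        if (any(f > frac)) {
          stacked_idx[i] <- TRUE
          next
        }
      }
      kept <- c(kept, i)
    }
  }
  retained <- blocks[!stacked_idx, , drop = FALSE]
  stacked <- blocks[stacked_idx, , drop = FALSE]
  rownames(retained) <- rownames(stacked) <- NULL
  filter_outcome(retained, outcome$discarded,
                 rbind(outcome$stacked, stacked))
}

#' Filter blocks and set aside stacked ones in a single call
#'
#' @inheritParams filter_blocks
#' @return `filter_outcome` with all three partitions populated.
#' @export
apply_filters <- function(blocks, cfg = filter_config()) {
  detect_stacked(filter_blocks(blocks, cfg), cfg)
}
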