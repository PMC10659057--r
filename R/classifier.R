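#' Discrepancy category labels
#' @keywords internal
DISCREPANCY_LABELS <- c("debris", "translocation", "inversion", "relocation")

#' @keywords internal
ALL_LABELS <- c(DISCREPANCY_LABELS, "congruent")

#' Dominant target of a query chromosome
#'
#' The reference sequence receiving the maximum summed query-block bp from
#' the given query sequence. Ties break to the larger support, then to the
#' lexicographically smaller target name.
#'
#' @param blocks alignment-block table (retained blocks).
#' @param query_chr query sequence name.
#' @return list with `target` and `support_bp`.
#' @export
dominant_target <- function(blocks, query_chr) {
  sub <- blocks[blocks$query_name == query_chr, , drop = FALSE]
  if (nrow(sub) == 0)
    stop("no retained blocks from query sequence ", query_chr, call. = FALSE)
  bp <- tapply(query_span(sub), sub$target_name, sum)
  bp <- bp[order(-bp, names(bp))]
  list(target = names(bp)[1], support_bp = as.numeric(bp[1]))
}

#' Dominant strand of a target sequence
#'
#' The strand with maximum summed query-block bp on the given reference
#' sequence; an exact tie resolves to forward.
#'
#' @param blocks alignment-block table.
#' @param target_seq target sequence name.
#' @return `"+"` or `"-"`.
#' @export
dominant_strand <- function(blocks, target_seq) {
  sub <- blocks[blocks$target_name == target_seq, , drop = FALSE]
  if (nrow(sub) == 0)
    stop("no blocks on target sequence ", target_seq, call. = FALSE)
  fwd <- sum(query_span(sub)[sub$strand == "+"])
  rev <- sum(query_span(sub)[sub$strand == "-"])
  if (fwd >= rev) "+" else "-"
}

#' Maximum-weight increasing subsequence
#'
#' O(n^2) dynamic program over `values`, maximizing total `weights` over
#' strictly increasing subsequences. Ties in the DP resolve to the earliest
#' predecessor, making the selection deterministic for a fixed input order.
#'
#' @param values numeric vector (ordering key).
#' @param weights positive weights.
#' @return integer indices of the selected subsequence.
#' @keywords internal
max_weight_increasing_subsequence <- function(values, weights) {
  n <- length(values)
  if (n == 0) return(integer(0))
  best <- weights
  prev <- rep(0L, n)
  for (i in seq_len(n)[-1]) {
    cand <- which(values[seq_len(i - 1)] < values[i])
    if (length(cand) > 0) {
      j <- cand[which.max(best[cand])]
      best[i] <- weights[i] + best[j]
      prev[i] <- j
    }
  }
  i <- which.max(best)
  out <- integer(0)
  while (i > 0) {
    out <- c(i, out)
    i <- prev[i]
  }
  out
}

#' Collinear backbone of same-target, dominant-strand blocks
#'
#' Orders the blocks by query position (reversed when the dominant mapping
#' direction is reverse) and extracts the bp-weight-maximal subset whose
#' target_start values are strictly increasing — a weighted
#' longest-increasing-subsequence formalization of the collinear synteny
#' backbone. Blocks outside the backbone are "out of order": relocation
#' candidates.
#'
#' @param blocks alignment-block table sharing one target sequence, all on
#'   the dominant strand.
#' @param dominant `"+"` or `"-"`, the dominant strand of the target.
#' @return logical vector, `TRUE` for backbone members, parallel to rows.
#' @export
backbone <- function(blocks, dominant = "+") {
  n <- nrow(blocks)
  if (n == 0) return(logical(0))
  ord <- order(blocks$query_start, blocks$target_start,
               decreasing = c(dominant == "-", FALSE), method = "radix")
  keep <- max_weight_increasing_subsequence(
    blocks$target_start[ord], query_span(blocks)[ord])
  member <- logical(n)
  member[ord[keep]] <- TRUE
  member
}

#' Classify retained alignment blocks into discrepancy categories
#'
#' Assigns each retained block exactly one label by applying the category
#' criteria in fixed precedence order; each criterion only sees blocks not
#' yet labeled, so nested discrepancies are not stacked (an inversion inside
#' a translocated segment counts once, as translocation):
#'
#' 1. **debris** — the query sequence is unplaced debris while the target is
#'    a reference chromosome (`debris_side = "query"`, the default); the
#'    symmetric and two-sided accountings are available via `debris_side`.
#' 2. **translocation** — the query sequence is a chromosome and the block's
#'    target differs from the dominant target of that query chromosome.
#' 3. **inversion** — the block's strand differs from the dominant strand of
#'    its target sequence (computed over blocks surviving steps 1-2).
#' 4. **relocation** — the block falls outside the collinear [backbone()] of
#'    its (query, target) group.
#' 5. **congruent** — everything else.
#'
#' Blocks whose query and target are both debris are never debris-labeled
#' (the category requires one chromosome-assigned side); they fall through
#' to the strand/order criteria and end up congruent when collinear.
#'
#' @param retained alignment-block table that already passed
#'   [filter_blocks()] and [detect_stacked()].
#' @param query_catalog,ref_catalog `asm_catalog`s for the query and
#'   reference assemblies.
#' @param debris_side which side's debris status triggers the debris label:
#'   `"query"` (default), `"reference"`, or `"both"`.
#' @return the input table with `label` and `evidence` columns appended
#'   (input row order preserved).
#' @export
classify_blocks <- function(retained, query_catalog, ref_catalog,
                            debris_side = c("query", "reference", "both")) {
  debris_side <- match.arg(debris_side)
  validate_blocks(retained)
  q_status <- stats::setNames(query_catalog$sequences$status,
                              query_catalog$sequences$name)
  t_status <- stats::setNames(ref_catalog$sequences$status,
                              ref_catalog$sequences$name)
  unknown_q <- setdiff(unique(retained$query_name), names(q_status))
  if (length(unknown_q) > 0)
    stop("query catalog is missing sequence(s): ",
         paste(unknown_q, collapse = ", "), call. = FALSE)
  unknown_t <- setdiff(unique(retained$target_name), names(t_status))
  if (length(unknown_t) > 0)
    stop("reference catalog is missing sequence(s): ",
         paste(unknown_t, collapse = ", "), call. = FALSE)

  n <- nrow(retained)
  label <- rep(NA_character_, n)
  evidence <- rep("", n)
  if (n == 0) {
    retained$label <- character(0)
    retained$evidence <- character(0)
    return(retained)
  }
  qs <- q_status[retained$query_name]
  ts <- t_status[retained$target_name]
  span <- query_span(retained)

  ## 1. debris
  is_debris <- switch(
    debris_side,
    query = qs == "unplaced_debris" & ts == "chromosome",
    reference = qs == "chromosome" & ts == "unplaced_debris",
    both = (qs == "unplaced_debris" & ts == "chromosome") |
      (qs == "chromosome" & ts == "unplaced_debris")
  )
  label[is_debris] <- "debris"
  evidence[is_debris] <- ifelse(
    qs[is_debris] == "unplaced_debris",
    "query sequence is unplaced debris; target is a chromosome",
    "target sequence is unplaced debris; query is a chromosome"
  )

  ## 2. translocation (per query chromosome, vs its dominant target)
  open <- is.na(label)
  chrom_q <- open & qs == "chromosome"
  if (any(chrom_q)) {
    agg <- stats::aggregate(
      span[chrom_q],
      by = list(query = retained$query_name[chrom_q],
                target = retained$target_name[chrom_q]),
      FUN = sum)
    agg <- agg[order(agg$query, -agg$x, agg$target), , drop = FALSE]
    dom <- agg[!duplicated(agg$query), , drop = FALSE]
    dom_target <- stats::setNames(dom$target, dom$query)
    is_transloc <- chrom_q &
      retained$target_name != dom_target[retained$query_name]
    label[is_transloc] <- "translocation"
    evidence[is_transloc] <- sprintf(
      "target %s differs from dominant target %s of query %s",
      retained$target_name[is_transloc],
      dom_target[retained$query_name[is_transloc]],
      retained$query_name[is_transloc])
  }

  ## 3. inversion (per target sequence, vs its dominant strand)
  open <- is.na(label)
  dom_strand <- character(0)
  if (any(open)) {
    fwd <- tapply(span[open] * (retained$strand[open] == "+"),
                  retained$target_name[open], sum)
    rev <- tapply(span[open] * (retained$strand[open] == "-"),
                  retained$target_name[open], sum)
    dom_strand <- stats::setNames(ifelse(fwd >= rev, "+", "-"), names(fwd))
    is_inv <- open & retained$strand != dom_strand[retained$target_name]
    label[is_inv] <- "inversion"
    evidence[is_inv] <- sprintf(
      "strand %s opposes dominant strand %s of target %s",
      retained$strand[is_inv],
      dom_strand[retained$target_name[is_inv]],
      retained$target_name[is_inv])
  }

  ## 4. relocation (outside the collinear backbone of the query-target group)
  open <- is.na(label)
  if (any(open)) {
    idx_open <- which(open)
    groups <- split(idx_open,
                    paste(retained$query_name[idx_open],
                          retained$target_name[idx_open], sep = "\r"))
    for (g in groups) {
      dom <- dom_strand[retained$target_name[g[1]]]
      member <- backbone(retained[g, , drop = FALSE], dominant = dom)
      reloc <- g[!member]
      label[reloc] <- "relocation"
      evidence[reloc] <- sprintf(
        "outside the collinear backbone of query %s on target %s",
        retained$query_name[reloc], retained$target_name[reloc])
    }
  }

  ## 5. congruent
  open <- is.na(label)
  label[open] <- "congruent"
  evidence[open] <- "consistent chromosome, strand and order"

  retained$label <- label
  retained$evidence <- evidence
  retained
}

#' Write labeled blocks as a circos-style link table
#'
#' Exports one row per block (query sequence and span, target sequence and
#' span, strand, category) in a TSV consumable by circos-style plotting
#' tools. Coordinates are converted to 1-based inclusive at this boundary.
#'
#' @param labeled output of [classify_blocks()].
#' @param path output TSV path.
#' @export
write_circos_links <- function(labeled, path) {
  df <- data.frame(
    query = labeled$query_name,
    query_start = labeled$query_start + 1,
    query_end = labeled$query_end,
    target = labeled$target_name,
    target_start = labeled$target_start + 1,
    target_end = labeled$target_end,
    strand = labeled$strand,
    category = labeled$label
  )
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
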