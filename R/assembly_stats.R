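#' N50 and L50 of a length set
#'
#' Sorting lengths in decreasing order, L50 is the smallest number of
#' sequences whose cumulative length reaches half the total (an exact hit on
#' total/2 counts as reaching it), and N50 is the length of the L50-th
#' sequence. Definitions differ across tools on the tie case; the inclusive
#' rule is used here and exercised against a brute-force oracle in the tests.
#'
#' @param lengths numeric vector of sequence lengths.
#' @return list with `n50` and `l50`.
#' @export
n50_l50 <- function(lengths) {
  stopifnot(length(lengths) > 0, all(lengths > 0))
  s <- sort(lengths, decreasing = TRUE)
  k <- which(cumsum(s) >= sum(s) / 2)[1]
  list(n50 = s[k], l50 = k)
}

#' Contig lengths of a catalog
#'
#' Splits every sequence at its recorded gap runs; the pieces between gaps
#' (and the whole sequence, when gapless) are the contigs. Gap runs shorter
#' than the catalog's `min_gap_run` were never recorded, so they neither
#' split contigs nor count as gap residue.
#'
#' @param catalog an `asm_catalog`.
#' @return numeric vector of contig lengths.
#' @export
contig_lengths <- function(catalog) {
  gaps <- split(catalog$gaps, catalog$gaps$name)
  out <- lapply(seq_len(nrow(catalog$sequences)), function(i) {
    nm <- catalog$sequences$name[i]
    len <- catalog$sequences$length[i]
    g <- gaps[[nm]]
    if (is.null(g) || nrow(g) == 0) return(len)
    g <- g[order(g$start), , drop = FALSE]
    bounds <- c(0, as.vector(rbind(g$start, g$end)), len)
    pieces <- bounds[seq(2, length(bounds), 2)] -
      bounds[seq(1, length(bounds), 2)]
    pieces[pieces > 0]
  })
  unlist(out)
}

#' Contiguity statistics of an assembly
#'
#' Recomputes the standard contiguity panel from a catalog: total length,
#' scaffold and contig counts, gap percentage, maximum scaffold and contig
#' lengths, and scaffold- and contig-level N50/L50. Scaffold metrics run
#' over whole sequences; contig metrics over the gap-split pieces.
#'
#' @param catalog an `asm_catalog` (see [build_catalog()]).
#' @return object of class `asm_stats`.
#' @export
compute_stats <- function(catalog) {
  if (nrow(catalog$sequences) == 0) stop("empty catalog", call. = FALSE)
  scaff <- catalog$sequences$length
  contigs <- contig_lengths(catalog)
  gap_bp <- sum(catalog$gaps$end - catalog$gaps$start)
  s50 <- n50_l50(scaff)
  c50 <- n50_l50(contigs)
  structure(
    list(
      total_length = sum(scaff),
      n_scaffolds = length(scaff),
      n_contigs = length(contigs),
      gap_pct = 100 * gap_bp / sum(scaff),
      max_scaffold_len = max(scaff),
      max_contig_len = max(contigs),
      scaffold_n50 = s50$n50, scaffold_l50 = s50$l50,
      contig_n50 = c50$n50, contig_l50 = c50$l50
    ),
    class = "asm_stats"
  )
}

#' @export
print.asm_stats <- function(x, ...) {
  cat(sprintf(
    paste0("Assembly stats: %s bp in %d scaffolds / %d contigs\n",
           "  gaps %.3f%%; max scaffold %s, max contig %s\n",
           "  scaffold N50 %s (L50 %d); contig N50 %s (L50 %d)\n"),
    format(x$total_length, big.mark = ","), x$n_scaffolds, x$n_contigs,
    x$gap_pct, format(x$max_scaffold_len, big.mark = ","),
    format(x$max_contig_len, big.mark = ","),
    format(x$scaffold_n50, big.mark = ","), x$scaffold_l50,
    format(x$contig_n50, big.mark = ","), x$contig_l50))
  invisible(x)
}

#' Compare two assemblies' contiguity statistics
#'
#' Per-metric ratios (`b / a`) and percent change, with a direction label,
#' in the style of "assembly B reduced the contig count by 69.2%".
#'
#' @param a,b `asm_stats` objects (a = baseline).
#' @return data.frame with columns `metric`, `a`, `b`, `ratio`,
#'   `pct_change`, `direction`.
#' @export
compare_stats <- function(a, b) {
  metrics <- setdiff(names(a), character(0))
  vals_a <- unlist(a[metrics])
  vals_b <- unlist(b[metrics])
  ratio <- ifelse(vals_a == 0 & vals_b == 0, 1,
                  ifelse(vals_a == 0, NA_real_, vals_b / vals_a))
  pct_change <- 100 * (ratio - 1)
  data.frame(
    metric = metrics,
    a = as.numeric(vals_a),
    b = as.numeric(vals_b),
    ratio = as.numeric(ratio),
    pct_change = as.numeric(pct_change),
    direction = ifelse(is.na(ratio), "undefined",
                       ifelse(ratio < 1, "reduced",
                              ifelse(ratio > 1, "increased", "unchanged"))),
    stringsAsFactors = FALSE
  )
}
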