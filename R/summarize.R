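#' Round half-up
#'
#' Base R's `round()` rounds half to even; printed report tables use
#' conventional half-up rounding instead.
#' @param x numeric.
#' @param digits decimal places.
#' @return rounded numeric.
#' @export
round_half_up <- function(x, digits = 0) {
  p <- 10^digits
  sign(x) * floor(abs(x) * p + 0.5) / p
}

#' Printed-precision digits for a percentage
#'
#' Report tables print percentages with two decimals below 10% and one
#' decimal above; full precision is always retained in the table object and
#' its JSON export.
#' @keywords internal
printed_digits <- function(pct) ifelse(abs(pct) < 10, 2L, 1L)

TABLE_CATEGORIES <- c("debris", "translocation", "inversion", "relocation",
                      "unassessed", "congruent")

#' Construct a discrepancy table from per-category bp counts
#'
#' The machine form of a per-comparison discrepancy summary: base pairs and
#' percentages for debris, translocation, inversion, relocation, unassessed
#' and congruent, as a share of the evaluated reference. Percentages are
#' stored at full precision; `evaluated_total` defaults to the sum of the
#' category bp (the "evaluated" denominator).
#'
#' @param bp named numeric vector over the six categories (missing names
#'   count 0).
#' @param comparison label for the assembly pair, e.g. `"A_vs_B"`.
#' @param evaluated_total denominator bp; default `sum(bp)`.
#' @return object of class `discrepancy_table`: a data.frame with columns
#'   `category`, `bp`, `pct` plus attributes `evaluated_total` and
#'   `comparison`.
#' @export
discrepancy_table <- function(bp, comparison = "query_vs_reference",
                              evaluated_total = NULL) {
  full <- stats::setNames(numeric(length(TABLE_CATEGORIES)), TABLE_CATEGORIES)
  bad <- setdiff(names(bp), TABLE_CATEGORIES)
  if (length(bad) > 0)
    stop("unknown category: ", paste(bad, collapse = ", "), call. = FALSE)
  full[names(bp)] <- bp
  if (is.null(evaluated_total)) evaluated_total <- sum(full)
  if (evaluated_total <= 0)
    stop("evaluated total must be positive", call. = FALSE)
  tab <- data.frame(
    category = TABLE_CATEGORIES,
    bp = as.numeric(full),
    pct = 100 * as.numeric(full) / evaluated_total,
    stringsAsFactors = FALSE
  )
  structure(tab, class = c("discrepancy_table", "data.frame"),
            evaluated_total = evaluated_total, comparison = comparison)
}

#' @export
print.discrepancy_table <- function(x, ...) {
  cat(sprintf("Discrepancy table for %s (evaluated total %s bp)\n",
              attr(x, "comparison"),
              format(attr(x, "evaluated_total"), big.mark = ",")))
  shown <- data.frame(
    category = x$category,
    bp = format(x$bp, big.mark = ","),
    pct = sprintf("%.*f", printed_digits(x$pct), round_half_up(
      x$pct, printed_digits(x$pct)))
  )
  print(shown, row.names = FALSE)
  cat(sprintf("Total discrepancy: %.1f%%\n", total_discrepancy(x)))
  invisible(x)
}

#' Tally labeled blocks into a discrepancy table
#'
#' Sums query-block bp per label, adds discarded and stacked bp as
#' unassessed, and converts to percentages of the evaluated reference.
#' Under the default `"evaluated"` denominator the total is the sum of all
#' category bp; under `"assembly"` it is the reference assembly length, and
#' the unaligned remainder of the reference is folded into unassessed so the
#' table still partitions the total exactly.
#'
#' @param labeled output of [classify_blocks()].
#' @param outcome the `filter_outcome` that produced the retained blocks
#'   (supplies discarded and stacked bp).
#' @param ref_catalog reference `asm_catalog` (used by the `"assembly"`
#'   denominator).
#' @param comparison label for the assembly pair.
#' @param denominator `"evaluated"` or `"assembly"`.
#' @return a [discrepancy_table()].
#' @export
tally <- function(labeled, outcome, ref_catalog = NULL,
                  comparison = "query_vs_reference",
                  denominator = c("evaluated", "assembly")) {
  denominator <- match.arg(denominator)
  bp <- stats::setNames(numeric(length(ALL_LABELS)), ALL_LABELS)
  if (nrow(labeled) > 0) {
    sums <- tapply(query_span(labeled), labeled$label, sum)
    bp[names(sums)] <- sums
  }
  unassessed <- sum(query_span(outcome$discarded)) +
    sum(query_span(outcome$stacked))
  total <- if (denominator == "assembly") {
    if (is.null(ref_catalog))
      stop("assembly denominator requires a reference catalog", call. = FALSE)
    ref_catalog$total_length
  } else {
    sum(bp) + unassessed
  }
  if (denominator == "assembly") {
    ## unaligned reference residue is unassessed by definition
    unassessed <- unassessed + (total - sum(bp) - unassessed)
  }
  discrepancy_table(c(bp, unassessed = unassessed), comparison = comparison,
                    evaluated_total = total)
}

#' Total discrepancy percentage
#'
#' The sum of the four discrepancy-category percentages (debris,
#' translocation, inversion, relocation), rounded half-up at the printed
#' precision.
#'
#' @param table a [discrepancy_table()].
#' @param digits decimal places of the printed total.
#' @return numeric scalar, percent.
#' @export
total_discrepancy <- function(table, digits = 1) {
  round_half_up(
    sum(table$pct[table$category %in% DISCREPANCY_LABELS]), digits)
}

#' Per-chromosome discrepancy and repeat profiles
#'
#' For every reference chromosome: length, summed bp of discrepancy-labeled
#' blocks projected onto it, the merged repeat bp of the annotation track,
#' and both as percentages of chromosome length.
#'
#' @param labeled output of [classify_blocks()].
#' @param ref_catalog reference `asm_catalog`.
#' @param repeats a `repeat_track` on the reference.
#' @return data.frame with columns `chromosome`, `length`, `discrepancy_bp`,
#'   `discrepancy_pct`, `repeat_bp`, `repeat_pct`, `is_x`.
#' @export
chromosome_profiles <- function(labeled, ref_catalog, repeats) {
  chrs <- ref_catalog$sequences[ref_catalog$sequences$status == "chromosome", ,
                                drop = FALSE]
  disc <- stats::setNames(numeric(nrow(chrs)), chrs$name)
  hit <- labeled$label %in% DISCREPANCY_LABELS &
    labeled$target_name %in% chrs$name
  if (any(hit)) {
    sums <- tapply(query_span(labeled)[hit], labeled$target_name[hit], sum)
    disc[names(sums)] <- sums
  }
  rep_bp <- repeat_bp(repeats, chrs$name)
  data.frame(
    chromosome = chrs$name,
    length = chrs$length,
    discrepancy_bp = as.numeric(disc),
    discrepancy_pct = 100 * as.numeric(disc) / chrs$length,
    repeat_bp = as.numeric(rep_bp),
    repeat_pct = 100 * as.numeric(rep_bp) / chrs$length,
    is_x = chrs$is_x,
    stringsAsFactors = FALSE
  )
}

#' Regress per-chromosome discrepancy on repeat density
#'
#' Ordinary least squares of discrepancy percentage on repeat percentage
#' across chromosomes, with a two-sided t-test on the slope and a Bonferroni
#' correction for the number of pairwise assembly comparisons in the run
#' (`alpha_corrected = 0.05 / n_comparisons`). The X chromosome, typically
#' repeat-enriched and discrepancy-enriched, can be excluded to probe whether
#' the association hinges on that single point.
#'
#' @param profiles output of [chromosome_profiles()].
#' @param exclude_x drop the X-flagged chromosome(s) before fitting.
#' @param n_comparisons number of pairwise comparisons for the Bonferroni
#'   correction.
#' @return object of class `regression_result`: list with `slope`,
#'   `intercept`, `r_squared`, `p_value`, `slope_se`, `n_chromosomes`,
#'   `alpha_corrected`, `significant`, `excluded_x`.
#' @export
regress <- function(profiles, exclude_x = FALSE, n_comparisons = 1) {
  pts <- if (exclude_x) profiles[!profiles$is_x, , drop = FALSE] else profiles
  if (nrow(pts) < 3)
    stop("regression requires at least 3 chromosomes", call. = FALSE)
  if (stats::var(pts$repeat_pct) == 0)
    stop("zero variance in repeat percentage", call. = FALSE)
  fit <- stats::lm(discrepancy_pct ~ repeat_pct, data = pts)
  sm <- summary(fit)
  alpha <- 0.05 / n_comparisons
  p <- sm$coefficients["repeat_pct", "Pr(>|t|)"]
  structure(
    list(
      slope = unname(stats::coef(fit)["repeat_pct"]),
      intercept = unname(stats::coef(fit)["(Intercept)"]),
      r_squared = sm$r.squared,
      p_value = p,
      slope_se = sm$coefficients["repeat_pct", "Std. Error"],
      n_chromosomes = nrow(pts),
      alpha_corrected = alpha,
      significant = p < alpha,
      excluded_x = isTRUE(exclude_x)
    ),
    class = "regression_result"
  )
}

#' @export
print.regression_result <- function(x, ...) {
  cat(sprintf(
    paste0("Discrepancy ~ repeat density OLS (n = %d chromosomes%s):\n",
           "  slope %.4f (SE %.4f), intercept %.4f, r^2 = %.3f\n",
           "  p = %.4g vs Bonferroni alpha %.4g -> %s\n"),
    x$n_chromosomes, if (x$excluded_x) ", X excluded" else "",
    x$slope, x$slope_se, x$intercept, x$r_squared, x$p_value,
    x$alpha_corrected,
    if (x$significant) "significant" else "not significant"))
  invisible(x)
}

#' Write a discrepancy table as TSV and JSON
#'
#' The TSV mirrors the per-category bp / percentage layout at printed
#' precision (half-up, two decimals below 10%, one above); the JSON carries
#' full precision and round-trips through [read_report_json()].
#'
#' @param table a [discrepancy_table()].
#' @param path_prefix output path prefix; writes `<prefix>.tsv` and
#'   `<prefix>.json`.
#' @return invisible character vector of the two paths.
#' @export
write_report <- function(table, path_prefix) {
  tsv <- paste0(path_prefix, ".tsv")
  json <- paste0(path_prefix, ".json")
  printed <- data.frame(
    category = table$category,
    bp = format(table$bp, scientific = FALSE, trim = TRUE),
    pct = sprintf("%.*f", printed_digits(table$pct),
                  round_half_up(table$pct, printed_digits(table$pct)))
  )
  utils::write.table(printed, tsv, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  jsonlite::write_json(
    list(comparison = attr(table, "comparison"),
         evaluated_total = attr(table, "evaluated_total"),
         categories = data.frame(category = table$category, bp = table$bp,
                                 pct = table$pct),
         total_discrepancy_pct = total_discrepancy(table)),
    json, auto_unbox = TRUE, digits = NA)
  invisible(c(tsv, json))
}

#' Reload a discrepancy table written by [write_report()]
#'
#' @param path path to the JSON report.
#' @return a [discrepancy_table()].
#' @export
read_report_json <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  discrepancy_table(
    stats::setNames(obj$categories$bp, obj$categories$category),
    comparison = obj$comparison,
    evaluated_total = obj$evaluated_total
  )
}
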