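#' Repeat track
#'
#' Per-sequence sorted, merged intervals of repeat elements (0-based
#' half-open), used to compute per-chromosome repeat density. Repeat
#' annotation itself (e.g. RepeatMasker output converted to BED) is an input;
#' soft-masked lowercase bases are deliberately ignored so that masking
#' dialects cannot leak into classification.
#'
#' @param intervals data.frame with columns `name`, `start`, `end`.
#' @param n_skipped count of input intervals dropped (unknown sequence).
#' @return object of class `repeat_track`.
#' @export
repeat_track <- function(intervals = data.frame(name = character(0),
                                                start = numeric(0),
                                                end = numeric(0)),
                         n_skipped = 0L) {
  structure(list(intervals = intervals, n_skipped = n_skipped),
            class = "repeat_track")
}

#' @export
print.repeat_track <- function(x, ...) {
  cat(sprintf("Repeat track: %d merged intervals, %s bp total\n",
              nrow(x$intervals),
              format(sum(x$intervals$end - x$intervals$start),
                     big.mark = ",")))
  invisible(x)
}

#' @keywords internal
merge_intervals <- function(df) {
  if (nrow(df) == 0) return(df)
  out <- lapply(split(df, df$name), function(d) {
    r <- IRanges::reduce(IRanges::IRanges(start = d$start + 1, end = d$end))
    data.frame(name = d$name[1], start = IRanges::start(r) - 1,
               end = IRanges::end(r))
  })
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res[order(res$name, res$start), , drop = FALSE]
}

#' Read a repeat annotation from BED
#'
#' Consumes BED3+ (0-based half-open) intervals, drops intervals on sequences
#' absent from the catalog (with a warning and a skip count), clips to
#' sequence bounds, sorts, and merges overlaps.
#'
#' @param bed path to a BED file.
#' @param catalog `asm_catalog` of the annotated assembly.
#' @return a `repeat_track`.
#' @export
read_repeat_track <- function(bed, catalog) {
  lines <- readLines(bed, warn = FALSE)
  lines <- lines[nzchar(lines) & !startsWith(lines, "#") &
                   !startsWith(lines, "track")]
  if (length(lines) == 0) return(repeat_track())
  fields <- strsplit(lines, "\t", fixed = TRUE)
  if (any(vapply(fields, length, integer(1)) < 3))
    stop("malformed BED line: fewer than 3 fields", call. = FALSE)
  intervals <- data.frame(
    name = vapply(fields, `[`, character(1), 1),
    start = as.numeric(vapply(fields, `[`, character(1), 2)),
    end = as.numeric(vapply(fields, `[`, character(1), 3)),
    stringsAsFactors = FALSE
  )
  if (anyNA(intervals$start) || anyNA(intervals$end))
    stop("malformed BED line: non-numeric coordinate", call. = FALSE)
  repeat_track_from_intervals(intervals, catalog)
}

#' Build a repeat track from an interval table
#'
#' @param intervals data.frame (`name`, `start`, `end`), 0-based half-open.
#' @param catalog `asm_catalog` providing sequence bounds.
#' @return a `repeat_track`.
#' @export
repeat_track_from_intervals <- function(intervals, catalog) {
  stopifnot(all(c("name", "start", "end") %in% names(intervals)))
  if (nrow(intervals) == 0) return(repeat_track())
  if (any(intervals$start >= intervals$end))
    stop("repeat interval with start >= end", call. = FALSE)
  known <- intervals$name %in% catalog$sequences$name
  n_skipped <- sum(!known)
  if (n_skipped > 0) {
    warning(sprintf("skipped %d repeat interval(s) on unknown sequence(s): %s",
                    n_skipped,
                    paste(unique(intervals$name[!known]), collapse = ", ")),
            call. = FALSE)
    intervals <- intervals[known, , drop = FALSE]
  }
  if (nrow(intervals) == 0) return(repeat_track(n_skipped = n_skipped))
  len <- stats::setNames(catalog$sequences$length, catalog$sequences$name)
  intervals$start <- pmax(intervals$start, 0)
  intervals$end <- pmin(intervals$end, len[intervals$name])
  intervals <- intervals[intervals$start < intervals$end, , drop = FALSE]
  repeat_track(merge_intervals(intervals[, c("name", "start", "end")]),
               n_skipped = n_skipped)
}

#' Repeat bp per sequence
#'
#' @param track a `repeat_track`.
#' @param names sequence names to report (missing names report 0).
#' @return named numeric vector of merged repeat bp.
#' @export
repeat_bp <- function(track, names) {
  bp <- stats::setNames(numeric(length(names)), names)
  if (nrow(track$intervals) > 0) {
    sums <- tapply(track$intervals$end - track$intervals$start,
                   track$intervals$name, sum)
    hit <- intersect(names, names(sums))
    bp[hit] <- as.numeric(sums[hit])
  }
  bp
}
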