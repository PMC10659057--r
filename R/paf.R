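#' Column names of the mandatory PAF fields
#'
#' Canonical column order used by every function in the package that consumes
#' or produces alignment-block tables.
#' @keywords internal
PAF_COLUMNS <- c(
  "query_name", "query_seq_len", "query_start", "query_end", "strand",
  "target_name", "target_seq_len", "target_start", "target_end",
  "residue_matches", "block_len", "mapq"
)

#' Construct an alignment-block table
#'
#' Builds a validated data.frame of alignment blocks, one row per PAF record.
#' Coordinates follow the PAF convention: 0-based, half-open, so a block
#' covering the first 100 bases of a sequence has `start = 0`, `end = 100`.
#'
#' @param query_name,target_name character sequence identifiers.
#' @param query_seq_len,target_seq_len full sequence lengths in bp (PAF
#'   columns 2 and 7 — not the aligned span).
#' @param query_start,query_end,target_start,target_end 0-based half-open
#'   aligned intervals.
#' @param strand `"+"` or `"-"`.
#' @param residue_matches number of matching bases in the block (PAF col 10).
#' @param block_len alignment block length in bp (PAF col 11).
#' @param mapq mapping quality, 0-255.
#' @return data.frame with the 12 mandatory PAF columns.
#' @export
alignment_blocks <- function(query_name, query_seq_len, query_start, query_end,
                             strand, target_name, target_seq_len, target_start,
                             target_end, residue_matches, block_len, mapq) {
  df <- data.frame(
    query_name = as.character(query_name),
    query_seq_len = as.numeric(query_seq_len),
    query_start = as.numeric(query_start),
    query_end = as.numeric(query_end),
    strand = as.character(strand),
    target_name = as.character(target_name),
    target_seq_len = as.numeric(target_seq_len),
    target_start = as.numeric(target_start),
    target_end = as.numeric(target_end),
    residue_matches = as.numeric(residue_matches),
    block_len = as.numeric(block_len),
    mapq = as.numeric(mapq),
    stringsAsFactors = FALSE
  )
  validate_blocks(df)
  df
}

#' @keywords internal
validate_blocks <- function(blocks) {
  stopifnot(is.data.frame(blocks))
  missing <- setdiff(PAF_COLUMNS, names(blocks))
  if (length(missing) > 0) {
    stop("alignment-block table is missing columns: ",
         paste(missing, collapse = ", "), call. = FALSE)
  }
  if (nrow(blocks) == 0) return(invisible(blocks))
  with(blocks, {
    if (any(!strand %in% c("+", "-")))
      stop("strand must be '+' or '-'", call. = FALSE)
    if (any(query_start < 0 | query_start >= query_end |
            query_end > query_seq_len))
      stop("query interval out of bounds: need 0 <= start < end <= seq_len",
           call. = FALSE)
    if (any(target_start < 0 | target_start >= target_end |
            target_end > target_seq_len))
      stop("target interval out of bounds: need 0 <= start < end <= seq_len",
           call. = FALSE)
    if (any(residue_matches > block_len))
      stop("residue_matches must not exceed block_len", call. = FALSE)
    if (any(mapq < 0 | mapq > 255))
      stop("mapq must lie in [0, 255]", call. = FALSE)
  })
  invisible(blocks)
}

#' Read a PAF alignment file
#'
#' Parses the 12 mandatory tab-separated PAF columns into an alignment-block
#' table; optional SAM-style tags beyond column 12 are ignored. Line order is
#' preserved. An empty file yields a zero-row table.
#'
#' @param path path to a PAF file (minimap2 dialect).
#' @return data.frame of alignment blocks (see [alignment_blocks()]).
#' @export
read_paf <- function(path) {
  if (!file.exists(path)) stop("PAF file not found: ", path, call. = FALSE)
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(lines)]
  if (length(lines) == 0) return(empty_blocks())
  fields <- strsplit(lines, "\t", fixed = TRUE)
  n <- vapply(fields, length, integer(1))
  if (any(n < 12)) {
    stop("malformed PAF line ", which(n < 12)[1],
         ": fewer than 12 tab-separated fields", call. = FALSE)
  }
  m <- t(vapply(fields, function(f) f[1:12], character(12)))
  num_cols <- c(2, 3, 4, 7, 8, 9, 10, 11, 12)
  nums <- suppressWarnings(
    lapply(num_cols, function(j) as.numeric(m[, j]))
  )
  bad <- which(Reduce(`|`, lapply(nums, is.na)))
  if (length(bad) > 0) {
    stop("malformed PAF line ", bad[1], ": non-numeric coordinate field",
         call. = FALSE)
  }
  if (any(!m[, 5] %in% c("+", "-"))) {
    stop("malformed PAF line ", which(!m[, 5] %in% c("+", "-"))[1],
         ": strand must be '+' or '-'", call. = FALSE)
  }
  alignment_blocks(
    query_name = m[, 1], query_seq_len = nums[[1]],
    query_start = nums[[2]], query_end = nums[[3]],
    strand = m[, 5],
    target_name = m[, 6], target_seq_len = nums[[4]],
    target_start = nums[[5]], target_end = nums[[6]],
    residue_matches = nums[[7]], block_len = nums[[8]], mapq = nums[[9]]
  )
}

#' Write an alignment-block table as PAF
#'
#' Writes the 12 mandatory PAF columns, tab-separated, one block per line.
#' Round-trips losslessly through [read_paf()].
#'
#' @param blocks alignment-block table.
#' @param path output path.
#' @export
write_paf <- function(blocks, path) {
  validate_blocks(blocks)
  out <- blocks[, PAF_COLUMNS]
  for (col in setdiff(PAF_COLUMNS, c("query_name", "strand", "target_name"))) {
    out[[col]] <- format(out[[col]], scientific = FALSE, trim = TRUE)
  }
  utils::write.table(out, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' @keywords internal
empty_blocks <- function() {
  alignment_blocks(
    query_name = character(0), query_seq_len = numeric(0),
    query_start = numeric(0), query_end = numeric(0),
    strand = character(0), target_name = character(0),
    target_seq_len = numeric(0), target_start = numeric(0),
    target_end = numeric(0), residue_matches = numeric(0),
    block_len = numeric(0), mapq = numeric(0)
  )
}

#' Query span of each block in bp
#'
#' The per-category base-pair tallies sum the length of the query-side
#' aligned interval of each block (`query_end - query_start`), which for
#' gapless alignments equals the block length.
#' @param blocks alignment-block table.
#' @return numeric vector of spans.
#' @keywords internal
query_span <- function(blocks) {
  if (nrow(blocks) == 0) return(numeric(0))
  blocks$query_end - blocks$query_start
}
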