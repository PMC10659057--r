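#' Assembly catalog
#'
#' A registry of the sequences making up one assembly: name, length, status
#' (`"chromosome"` or `"unplaced_debris"`), an X-chromosome flag, and the gap
#' intervals (maximal runs of N of at least `min_gap_run` bases, 0-based
#' half-open). Chromosome-scale scaffolds and small unplaced "debris"
#' sequences are distinguished because discrepancy classification treats
#' alignments from debris onto reference chromosomes as their own category.
#'
#' @param sequences data.frame with columns `name`, `length`, `status`
#'   (`"chromosome"`/`"unplaced_debris"`), `is_x` (logical).
#' @param gaps data.frame with columns `name`, `start`, `end` (0-based
#'   half-open N-runs), zero rows if gapless.
#' @param min_gap_run minimum N-run length recorded as a gap.
#' @return object of class `asm_catalog`.
#' @export
assembly_catalog <- function(sequences,
                             gaps = data.frame(name = character(0),
                                               start = numeric(0),
                                               end = numeric(0)),
                             min_gap_run = 10) {
  stopifnot(all(c("name", "length") %in% names(sequences)))
  if (nrow(sequences) == 0) stop("catalog must contain at least one sequence",
                                 call. = FALSE)
  if (anyDuplicated(sequences$name))
    stop("duplicate sequence names in catalog: ",
         paste(unique(sequences$name[duplicated(sequences$name)]),
               collapse = ", "), call. = FALSE)
  if (is.null(sequences$status)) sequences$status <- "chromosome"
  if (is.null(sequences$is_x)) sequences$is_x <- FALSE
  bad <- setdiff(unique(sequences$status), c("chromosome", "unplaced_debris"))
  if (length(bad) > 0)
    stop("unknown sequence status: ", paste(bad, collapse = ", "),
         call. = FALSE)
  if (nrow(gaps) > 0) {
    len <- stats::setNames(sequences$length, sequences$name)
    if (any(!gaps$name %in% sequences$name))
      stop("gap interval on unknown sequence", call. = FALSE)
    if (any(gaps$start < 0 | gaps$start >= gaps$end |
            gaps$end > len[gaps$name]))
      stop("gap interval out of sequence bounds", call. = FALSE)
  }
  structure(
    list(
      sequences = sequences[, c("name", "length", "status", "is_x")],
      gaps = gaps[, c("name", "start", "end")],
      min_gap_run = min_gap_run,
      total_length = sum(sequences$length)
    ),
    class = "asm_catalog"
  )
}

#' @export
print.asm_catalog <- function(x, ...) {
  n_chr <- sum(x$sequences$status == "chromosome")
  cat(sprintf(
    "Assembly catalog: %d sequences (%d chromosome, %d debris), %s bp, %d gaps\n",
    nrow(x$sequences), n_chr, nrow(x$sequences) - n_chr,
    format(x$total_length, big.mark = ","), nrow(x$gaps)))
  invisible(x)
}

#' Locate gap intervals (runs of N) in a sequence set
#'
#' @param seqs named character vector or `Biostrings::DNAStringSet`.
#' @param min_gap_run minimum run of N/n counted as a gap.
#' @return data.frame (`name`, `start`, `end`), 0-based half-open.
#' @keywords internal
find_gap_runs <- function(seqs, min_gap_run = 10) {
  if (methods::is(seqs, "DNAStringSet")) seqs <- as.character(seqs)
  out <- lapply(names(seqs), function(nm) {
    hits <- gregexpr(sprintf("[Nn]{%d,}", min_gap_run), seqs[[nm]])[[1]]
    if (hits[1] == -1) return(NULL)
    data.frame(name = nm,
               start = as.numeric(hits) - 1,
               end = as.numeric(hits) - 1 + attr(hits, "match.length"))
  })
  out <- out[!vapply(out, is.null, logical(1))]
  if (length(out) == 0)
    return(data.frame(name = character(0), start = numeric(0),
                      end = numeric(0)))
  do.call(rbind, out)
}

#' Build an assembly catalog from a FASTA file
#'
#' Reads the assembly, locates gap runs, and assigns each sequence a status.
#' Status assignment follows either an explicit chromosome name list or a
#' minimum-length rule (sequences at least `min_chromosome_len` bp are
#' chromosomes, the rest unplaced debris). The default 10 Mbp threshold
#' cleanly separates chromosome-scale scaffolds from debris in mammalian
#' assemblies; supply `chromosome_names` when working with toy genomes.
#'
#' @param fasta path to a FASTA file, or a `Biostrings::DNAStringSet`.
#' @param chromosome_names explicit character vector of chromosome-status
#'   sequence names, or `NULL` to use the length rule.
#' @param min_chromosome_len length threshold used when `chromosome_names`
#'   is `NULL`.
#' @param x_name name of the X chromosome, or `NULL` if unknown.
#' @param min_gap_run minimum N-run length recorded as a gap (default 10,
#'   the lower end of the typical 10-100 N spacer length).
#' @return an `asm_catalog`.
#' @export
build_catalog <- function(fasta, chromosome_names = NULL,
                          min_chromosome_len = 1e7, x_name = NULL,
                          min_gap_run = 10) {
  if (methods::is(fasta, "DNAStringSet")) {
    seqs <- fasta
  } else {
    seqs <- Biostrings::readDNAStringSet(fasta)
    names(seqs) <- sub("\\s.*$", "", names(seqs))
  }
  if (length(seqs) == 0) stop("empty FASTA: no sequences", call. = FALSE)
  if (anyDuplicated(names(seqs)))
    stop("duplicate sequence names in FASTA", call. = FALSE)
  lens <- Biostrings::width(seqs)
  status <- if (is.null(chromosome_names)) {
    ifelse(lens >= min_chromosome_len, "chromosome", "unplaced_debris")
  } else {
    ifelse(names(seqs) %in% chromosome_names, "chromosome", "unplaced_debris")
  }
  sequences <- data.frame(
    name = names(seqs), length = as.numeric(lens), status = status,
    is_x = if (is.null(x_name)) FALSE else names(seqs) == x_name,
    stringsAsFactors = FALSE
  )
  gaps <- find_gap_runs(seqs, min_gap_run)
  assembly_catalog(sequences, gaps, min_gap_run = min_gap_run)
}

#' Sequence names with chromosome status
#' @param catalog an `asm_catalog`.
#' @return character vector.
#' @export
chromosome_names <- function(catalog) {
  catalog$sequences$name[catalog$sequences$status == "chromosome"]
}
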