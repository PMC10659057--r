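#' Published per-category discrepancy bp for the monodontid comparisons
#'
#' The per-category base-pair counts reported for the published
#' beluga/narwhal assembly comparisons (four beluga assemblies against the
#' most contiguous one, Dl_5_, and the narwhal Mm_Damas_ assembly against
#' Mm_3_), shipped as plain-text input data so the percentage arithmetic can
#' be recomputed without any download.
#'
#' @return data.frame with columns `assembly`, `species`, `reference`, and
#'   bp columns `debris`, `translocation`, `inversion`, `relocation`,
#'   `unassessed`, `congruent`.
#' @export
monodontid_category_bp <- function() {
  utils::read.table(
    system.file("extdata", "monodontid_category_bp.tsv",
                package = "asmcompare", mustWork = TRUE),
    sep = "\t", header = TRUE, stringsAsFactors = FALSE)
}

#' Published contiguity statistics for the monodontid assemblies
#'
#' Total length, contig/scaffold counts, gap percentage, maximum lengths and
#' N50/L50 for the published beluga and narwhal assemblies, as plain-text
#' input data (lengths in Mbp as printed).
#'
#' @return data.frame, one row per assembly.
#' @export
monodontid_assembly_stats <- function() {
  utils::read.table(
    system.file("extdata", "monodontid_assembly_stats.tsv",
                package = "asmcompare", mustWork = TRUE),
    sep = "\t", header = TRUE, stringsAsFactors = FALSE)
}

#' Discrepancy tables for every published comparison
#'
#' Runs [discrepancy_table()] over each row of [monodontid_category_bp()].
#'
#' @return named list of `discrepancy_table` objects.
#' @export
monodontid_discrepancy_tables <- function() {
  bp <- monodontid_category_bp()
  out <- lapply(seq_len(nrow(bp)), function(i) {
    discrepancy_table(
      c(debris = bp$debris[i], translocation = bp$translocation[i],
        inversion = bp$inversion[i], relocation = bp$relocation[i],
        unassessed = bp$unassessed[i], congruent = bp$congruent[i]),
      comparison = paste0(bp$assembly[i], "_vs_", bp$reference[i]))
  })
  stats::setNames(out, bp$assembly)
}
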