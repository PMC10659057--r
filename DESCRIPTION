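Package: asmcompare
Title: Screening Structural Discrepancies Between Reference Genome Assemblies
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Compares pairs of reference genome assemblies from whole-genome
    alignments in PAF format. Alignment blocks are filtered on query length,
    block length, mapping quality and identity, screened for stacked blocks,
    and then classified into debris, translocation, inversion, relocation or
    congruent categories using dominant-target, dominant-strand and
    collinear-backbone criteria. Per-category base-pair tallies are reported
    as percentages of the evaluated reference, per-chromosome discrepancy
    profiles are regressed on repeat-element density, and contiguity
    statistics (N50, L50, gap content) are recomputed from FASTA. A seeded
    simulator implants ground-truthed inversions, translocations, relocations
    and debris fragments into toy genomes and emits idealized alignments so
    every stage is testable without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    Biostrings,
    IRanges,
    jsonlite,
    methods,
    optparse,
    stats,
    tools,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
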