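---
title: "Screening structural discrepancies between reference assemblies"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Screening structural discrepancies between reference assemblies}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(asmcompare)
```

## The problem

When the same genome is assembled twice — different sequencing chemistry,
different scaffolding data, different manual curation — the two
chromosome-scale products disagree. Some disagreement is real biology
(structural variation between individuals), some is assembly error; from a
pairwise comparison alone the two cannot be told apart, which is why this
package speaks of *discrepancies* rather than errors. What can be done
rigorously is to quantify the disagreement: align the two assemblies, and
assign every aligned block to a category describing *how* it disagrees.

`asmcompare` implements that screen for PAF alignments (minimap2 `asm5`
output is the intended producer; alignment itself is outside the package).
This vignette records the model, the parameters that matter, the numerical
and design choices made where the procedure was genuinely open, and what the
synthetic tests do and do not demonstrate.

## Block filtering

A PAF record carries both the full query sequence length (column 2) and the
alignment block length (column 11); the filters use both. A block is
discarded iff

* full query sequence length < 3,000 bp (`min_query_seq_len`) — tiny
  scaffolds carry no reliable structural signal;
* alignment block length < 500 bp (`min_block_len`);
* mapQ < 30 (`min_mapq`) — about a 1/1000 chance of mismapping;
* residue matches / block length < 0.8 (`min_match_fraction`).

All comparisons are strict, so a block sitting exactly on a threshold is
retained. Each discarded block records its first failing reason in the order
above. For comparisons against a highly fragmented assembly an additional
query-length floor of 1 Mbp (`fragmented = TRUE`) suppresses the flood of
short-scaffold alignments that would otherwise dominate the debris and
translocation tallies.

After filtering, *stacked* blocks are set aside: whenever two retained
blocks on the same query sequence overlap by more than 50% of the shorter
one (`stacked_overlap_fraction`, measured in query coordinates), the shorter
is removed, repeatedly until no such pair remains. Because "repeatedly" is
ambiguous for transitive pile-ups, the rule is realized as a deterministic
greedy pass in a fixed priority order — longer query span, then more residue
matches, then lexicographically smaller (target, target start), then query
start — which makes the outcome independent of input order; the tests verify
the fixed-point property directly. Discarded and stacked bp count as
unassessed, never as discrepancy.

## Classification

Retained blocks are labeled in fixed precedence, each criterion seeing only
blocks not yet labeled — so a nested discrepancy (an inversion inside a
translocated segment, say) is counted once, under the outer category:

1. **debris** — the query sequence is an unplaced fragment while the target
   is a reference chromosome. Which side's debris to count is a reporting
   choice (`debris_side`), because a comparison where one assembly was never
   chromosome-scaffolded has debris on one side only; the default counts
   query-side debris. Blocks whose query *and* target are both unplaced are
   never debris: the category describes sequence one assembly placed and the
   other did not.
2. **translocation** — the block's target differs from the *dominant target*
   of its query chromosome, the reference sequence receiving the most
   aligned bp from that chromosome (arg-max over the surviving blocks; ties
   break to the larger support, then the lexicographically smaller name).
   The frame is per query chromosome, matching the reading that a
   translocated segment is query sequence mapping to the "wrong" reference
   chromosome. Near-50/50 splits get no special treatment — arg-max with the
   deterministic tie-break — because any threshold would be arbitrary and
   the tie-break is at least reproducible.
3. **inversion** — the block's strand differs from the *dominant strand* of
   its target scaffold (bp arg-max over blocks surviving steps 1–2; an exact
   tie resolves to forward). Computing dominance after translocation removal
   is a deliberate ordering: foreign-chromosome blocks should not vote on a
   scaffold's mapping direction.
4. **relocation** — "out of order" is formalized as exclusion from the
   collinear backbone: within each (query, target) group, the
   bp-weight-maximal subset whose target start positions strictly increase
   when blocks are ordered by query position (query order reversed for
   reverse-dominant scaffolds), computed by weighted
   longest-increasing-subsequence (O(n²) dynamic program, earliest-index
   tie-break). LIS is the standard synteny-backbone formalization and is the
   one choice here that an exhaustive-enumeration oracle can certify, which
   the tests do for n ≤ 12.
5. **congruent** — everything else.

## Tallies, denominators, rounding

Per category, the query-side spans (`query_end − query_start`) of its blocks
are summed; unassessed adds discarded plus stacked bp. The percentage
denominator is a genuine ambiguity: the "total evaluated reference" can be
read as the sum of all category bp (so the table partitions exactly) or as
the nominal reference assembly length (in which case the unaligned remainder
is folded into unassessed to preserve the partition). Both are implemented
(`denominator = "evaluated"` / `"assembly"`); evaluated is the default. The
total discrepancy of a comparison is the sum of the four discrepancy-category
percentages, rounded half-up to one decimal.

Percentages are stored at full precision; only printing rounds, half-up
(base R's `round()` is banker's rounding, which published tables do not
use), two decimals below 10% and one above. JSON exports always carry full
precision and round-trip losslessly.

## Per-chromosome profiles and the repeat regression

Discrepancy bp are projected onto the reference chromosome each block aligns
to; repeat bp come from a BED annotation (e.g. RepeatMasker output),
clipped, sorted and merged, so duplicated or overlapping annotation
intervals cannot inflate density. Soft-masked lowercase bases are
deliberately ignored — repeats enter only through the track, keeping masking
dialects out of classification.

`regress()` fits discrepancy % on repeat % across chromosomes by OLS with a
two-sided t-test on the slope. Because a study typically makes several
pairwise comparisons, the significance threshold is Bonferroni-corrected:
`alpha_corrected = 0.05 / n_comparisons`. With five comparisons the
threshold is 0.01, so a comparison with p ≈ 0.025 is declared not
significant — the behavior expected when correcting a marginal association.
The X chromosome is both repeat- and discrepancy-enriched in mammalian
comparisons, so `exclude_x = TRUE` refits without it; a genome-wide
association that vanishes under X-exclusion was carried by a single point.
At least 3 points and nonzero predictor variance are required; violations
are errors, not silent NA.

## Contiguity statistics

`compute_stats()` recomputes the standard panel from FASTA: scaffold metrics
over whole sequences, contig metrics over pieces split at gap runs. A gap is
a maximal run of ≥ 10 Ns (`min_gap_run`; N spacers between contigs are
conventionally 10–100 bp, and the threshold is configurable because tools
disagree); shorter N runs neither split contigs nor count as gap residue.
N50/L50 use the inclusive crossing rule — a cumulative sum exactly equal to
half the total counts as crossing — documented because definitions differ
across tools, and checked against a brute-force sorted-prefix oracle.

## The simulator

`simulate_assembly_pair()` generates the study conditions in miniature so
that every stage is testable hermetically:

* **Genome**: 5 chromosomes totalling 10 Mbp (2.8/2.4/2.0/1.6/1.2 Mbp),
  uniform nucleotide composition, the smallest flagged as the X-like
  chromosome. Repeats are realized as tandem duplications of random 8–24 bp
  motifs — genuinely repetitive sequence, not just annotated intervals —
  placed to hit 35% density on autosomes and 55% on the X (mammalian
  genome-wide repeat content sits near 42%, with the X notably higher).
  Spacer lengths slightly overshoot the target density and the final
  interval is trimmed, pinning realized density at the target (tested
  within ±2 points).
* **Events**: 10 inversions, 5 translocations, 5 relocations, 5 debris
  fragments by default. Inversion sizes are log-normal with
  `meanlog = log(20000) + 0.885²`, `sdlog = 0.885`: the mode of a
  log-normal is `exp(meanlog − sdlog²)` = 20 kbp, and these parameters give
  `P(size > 100 kbp) = 0.175` — the midpoint of the observed 15–20%
  heavy-tail fraction of large inversions. Sizes are clamped to
  [5, 200] kbp. Translocation and relocation segments are uniform
  20–60 kbp; debris fragments uniform 15–100 kbp, the lower bound echoing
  the usual 15 kbp scaffolding-inclusion threshold below which fragments
  are relegated to debris, and keeping them far above the 3 kbp query
  filter.
* **Edits**: inversions reverse-complement in place; translocations move a
  window to another chromosome; relocations move a window out of order
  within its chromosome; debris windows are excised and emitted as
  standalone scaffolds. Events never overlap (overlapping requests are
  rejected, matching the no-stacking accounting) and keep a 20 kbp margin
  from ends and from each other so no flanking alignment falls below the
  block filters. A relocation's new position is additionally required to
  leave more aligned residue between old and new site than the segment
  itself, the condition under which the backbone provably keeps the flank
  and marks the moved copy. A 100 bp run of Ns marks every junction.
* **Alignments**: computed exactly from the edit history (matches = block
  length, mapQ 60), so classification tests are deterministic; optional
  fragmentation noise splits blocks at Poisson breakpoints (default rate
  1 per 100 kbp) without changing covered bp. Each emitted block carries
  its ground-truth category for recovery scoring.

With noise off, classification recovers every category's bp exactly; with
noise on, sub-blocks falling below the 500 bp filter cost a little recall,
and the tests require bp-level precision and recall ≥ 0.95 per category.
All outputs are pure functions of the configuration (including its seed).

**What passing these tests does not show**: the simulator has uniform base
composition, clean event boundaries, no segmental duplication, no
repeat-driven mismapping, and idealized alignments. Real minimap2 output
contains overlapping and chimeric blocks, mapping-quality noise, and genuine
biological variation; the filters and the stacked-block rule exist for those
data, but recovery rates measured here are upper bounds, not forecasts.

## Problem sizes and runtime choices

The test suite runs the full 10 Mbp default simulation in the end-to-end
blocks and a 1.8 Mbp four-chromosome configuration in unit tests; oracle
comparisons use 200–300 random blocks (filtering, stacking), n ≤ 12
(exhaustive backbone enumeration), 100 random length sets (N50/L50), and
100 planted-signal regression replicates of 22 chromosomes each. These sizes
were chosen to exercise every code path with brute-force-verifiable
instances while keeping the whole suite under a minute.

## Known limitations

* One label per block: nested discrepancies are attributed to the outermost
  category by design, so per-category bp are precedence-dependent.
* Debris accounting is side-dependent; cross-comparison tables mixing
  `debris_side` conventions are not comparable in that column.
* The published narwhal translocation cell (909,121 bp printed as 0.05%)
  is not reproducible from its own bp count under either denominator
  (both give ≈ 0.04%); the package reports the recomputed value.
* No attempt is made to separate biological structural variation from
  assembly error — the screen quantifies disagreement, not blame.
* The CLI takes its run configuration from flags only; a YAML/TOML config
  file was considered and dropped as redundant with the provenance record
  each run writes.
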