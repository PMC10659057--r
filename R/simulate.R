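#' Simulation configuration
#'
#' Parameters of the synthetic assembly-pair generator. The defaults emulate
#' the discrepancy landscape seen when comparing independently scaffolded
#' cetacean-style assemblies, scaled to a 10 Mbp toy genome: a handful of
#' chromosome-scale sequences plus a repeat-enriched X-like chromosome;
#' inversion sizes log-normal with mode near 20 kbp and a heavy tail putting
#' roughly 17.5% of events above 100 kbp; debris fragments of at least
#' 15 kbp (the usual scaffolding-inclusion threshold, so debris stays
#' distinguishable from filter-discarded noise); and runs of Ns at every
#' junction created by an edit.
#'
#' @param seed integer seed; every simulator output is a pure function of
#'   the configuration including this seed.
#' @param chromosome_lengths named numeric vector of chromosome lengths, bp.
#' @param x_name name of the repeat-enriched X-like chromosome.
#' @param n_inversions,n_translocations,n_relocations,n_debris event counts.
#' @param inversion_meanlog,inversion_sdlog log-normal parameters of the
#'   inversion size distribution (defaults give mode
#'   `exp(meanlog - sdlog^2) = 20` kbp and `P(size > 100 kbp) = 0.175`).
#' @param inversion_size_bounds clamp on sampled inversion sizes, bp.
#' @param translocation_size_range,relocation_size_range uniform size
#'   ranges, bp.
#' @param debris_size_range uniform debris fragment size range, bp.
#' @param gap_run_len length of the N run inserted at each derived junction.
#' @param autosome_repeat_pct,x_repeat_pct target repeat densities, percent.
#' @param repeat_interval_range uniform range of individual repeat interval
#'   lengths, bp.
#' @param repeat_unit_range uniform range of the tandem motif length, bp.
#' @param fragmentation_rate expected alignment breakpoints per bp when
#'   emitting noisy ideal alignments (default one per 100 kbp).
#' @param event_margin minimum distance between event windows and from
#'   chromosome ends, bp.
#' @return object of class `sim_config`.
#' @export
simulation_config <- function(seed = 1,
                              chromosome_lengths = c(chr1 = 2.8e6,
                                                     chr2 = 2.4e6,
                                                     chr3 = 2.0e6,
                                                     chr4 = 1.6e6,
                                                     chrX = 1.2e6),
                              x_name = "chrX",
                              n_inversions = 10,
                              n_translocations = 5,
                              n_relocations = 5,
                              n_debris = 5,
                              inversion_meanlog = log(2e4) + 0.885^2,
                              inversion_sdlog = 0.885,
                              inversion_size_bounds = c(5e3, 2e5),
                              translocation_size_range = c(2e4, 6e4),
                              relocation_size_range = c(2e4, 6e4),
                              debris_size_range = c(1.5e4, 1e5),
                              gap_run_len = 100,
                              autosome_repeat_pct = 35,
                              x_repeat_pct = 55,
                              repeat_interval_range = c(500, 5000),
                              repeat_unit_range = c(8, 24),
                              fragmentation_rate = 1e-5,
                              event_margin = 2e4) {
  stopifnot(length(chromosome_lengths) >= 2,
            !is.null(names(chromosome_lengths)),
            x_name %in% names(chromosome_lengths),
            autosome_repeat_pct >= 0, autosome_repeat_pct <= 100,
            x_repeat_pct >= 0, x_repeat_pct <= 100)
  structure(
    list(seed = as.integer(seed),
         chromosome_lengths = chromosome_lengths,
         x_name = x_name,
         n_inversions = n_inversions,
         n_translocations = n_translocations,
         n_relocations = n_relocations,
         n_debris = n_debris,
         inversion_meanlog = inversion_meanlog,
         inversion_sdlog = inversion_sdlog,
         inversion_size_bounds = inversion_size_bounds,
         translocation_size_range = translocation_size_range,
         relocation_size_range = relocation_size_range,
         debris_size_range = debris_size_range,
         gap_run_len = gap_run_len,
         autosome_repeat_pct = autosome_repeat_pct,
         x_repeat_pct = x_repeat_pct,
         repeat_interval_range = repeat_interval_range,
         repeat_unit_range = repeat_unit_range,
         fragmentation_rate = fragmentation_rate,
         event_margin = event_margin),
    class = "sim_config"
  )
}

#' @keywords internal
random_dna <- function(n) {
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}

#' @keywords internal
tandem_repeat <- function(width, unit_range) {
  unit_len <- sample(seq(unit_range[1], unit_range[2]), 1)
  unit <- random_dna(unit_len)
  substr(strrep(unit, ceiling(width / unit_len)), 1, width)
}

#' Place non-overlapping repeat intervals to a target density
#'
#' Walks along the sequence alternating random spacers and repeat intervals
#' until the target bp is reached; the final interval is trimmed so the
#' realized density matches the target exactly unless space runs out.
#' @keywords internal
place_repeat_intervals <- function(len, target_pct, interval_range) {
  target_bp <- round(len * target_pct / 100)
  if (target_bp <= 0) {
    return(data.frame(start = numeric(0), end = numeric(0)))
  }
  mean_interval <- mean(interval_range)
  ## spacers sized to overshoot the target slightly; the trim on the final
  ## interval then pins the realized density at the target
  mean_spacer <- max(10, 0.8 * mean_interval * (100 - target_pct) / target_pct)
  starts <- ends <- numeric(0)
  pos <- round(stats::runif(1, 0, 2 * mean_spacer))
  remaining <- target_bp
  while (remaining > 0 && pos < len) {
    w <- round(stats::runif(1, interval_range[1], interval_range[2]))
    w <- min(w, remaining, len - pos)
    if (w <= 0) break
    starts <- c(starts, pos)
    ends <- c(ends, pos + w)
    remaining <- remaining - w
    pos <- pos + w + round(stats::runif(1, 0.5 * mean_spacer,
                                        1.5 * mean_spacer))
  }
  data.frame(start = starts, end = ends)
}

#' Generate a seeded truth genome with a repeat track
#'
#' Builds a multi-chromosome random genome, realizes repeat elements as
#' tandem duplications of short random motifs placed to hit the configured
#' per-chromosome densities (elevated on the X-like chromosome), and returns
#' the sequences together with their catalog and repeat track. Reproducible:
#' the same configuration yields byte-identical output.
#'
#' @param cfg a [simulation_config()].
#' @return list with `genome` (`DNAStringSet`), `catalog` (`asm_catalog`),
#'   and `repeats` (`repeat_track`).
#' @export
generate_truth <- function(cfg) {
  set.seed(cfg$seed)
  lens <- cfg$chromosome_lengths
  min_event <- min(cfg$inversion_size_bounds[1],
                   cfg$translocation_size_range[1],
                   cfg$relocation_size_range[1], cfg$debris_size_range[1])
  if (any(lens < min_event + 2 * cfg$event_margin))
    stop("chromosome lengths too small for the requested events",
         call. = FALSE)
  seqs <- character(length(lens))
  rep_list <- vector("list", length(lens))
  for (i in seq_along(lens)) {
    nm <- names(lens)[i]
    bg <- random_dna(lens[i])
    pct <- if (nm == cfg$x_name) cfg$x_repeat_pct else cfg$autosome_repeat_pct
    iv <- place_repeat_intervals(lens[i], pct, cfg$repeat_interval_range)
    if (nrow(iv) > 0) {
      ## interleave background chunks with tandem-repeat realizations
      parts <- character(2 * nrow(iv) + 1)
      prev <- 0
      for (j in seq_len(nrow(iv))) {
        parts[2 * j - 1] <- substr(bg, prev + 1, iv$start[j])
        parts[2 * j] <- tandem_repeat(iv$end[j] - iv$start[j],
                                      cfg$repeat_unit_range)
        prev <- iv$end[j]
      }
      parts[2 * nrow(iv) + 1] <- substr(bg, prev + 1, lens[i])
      seqs[i] <- paste(parts, collapse = "")
      rep_list[[i]] <- data.frame(name = nm, start = iv$start, end = iv$end)
    } else {
      seqs[i] <- bg
    }
  }
  genome <- Biostrings::DNAStringSet(stats::setNames(seqs, names(lens)))
  catalog <- build_catalog(genome, chromosome_names = names(lens),
                           x_name = cfg$x_name)
  rep_df <- do.call(rbind, rep_list[!vapply(rep_list, is.null, logical(1))])
  if (is.null(rep_df))
    rep_df <- data.frame(name = character(0), start = numeric(0),
                         end = numeric(0))
  list(genome = genome, catalog = catalog,
       repeats = repeat_track_from_intervals(rep_df, catalog))
}

#' @keywords internal
sample_event_sizes <- function(cfg) {
  inv <- round(pmin(pmax(
    stats::rlnorm(cfg$n_inversions, cfg$inversion_meanlog,
                  cfg$inversion_sdlog),
    cfg$inversion_size_bounds[1]), cfg$inversion_size_bounds[2]))
  tra <- round(stats::runif(cfg$n_translocations,
                            cfg$translocation_size_range[1],
                            cfg$translocation_size_range[2]))
  rel <- round(stats::runif(cfg$n_relocations,
                            cfg$relocation_size_range[1],
                            cfg$relocation_size_range[2]))
  deb <- round(stats::runif(cfg$n_debris, cfg$debris_size_range[1],
                            cfg$debris_size_range[2]))
  data.frame(
    type = rep(c("inversion", "translocation", "relocation", "debris"),
               c(cfg$n_inversions, cfg$n_translocations, cfg$n_relocations,
                 cfg$n_debris)),
    length = c(inv, tra, rel, deb),
    stringsAsFactors = FALSE
  )
}

#' Implant ground-truthed structural events into a truth genome
#'
#' Derives a second assembly from the truth genome by applying
#' non-overlapping edits: inversions reverse-complement a window in place;
#' translocations move a window into a different chromosome; relocations
#' move a window out of order within its chromosome; debris excises a window
#' and emits it as a small standalone scaffold. A run of Ns is inserted at
#' every junction the edits create. Overlapping event requests are rejected;
#' placement keeps every window at least `event_margin` bp from chromosome
#' ends and from other windows so no alignment block is squeezed below the
#' retention filters.
#'
#' @param truth output of [generate_truth()].
#' @param cfg the same [simulation_config()].
#' @return list with `derived` (`DNAStringSet`), `catalog` (derived-side
#'   `asm_catalog`), `events` (the truth event table: `id`, `type`, `chr`,
#'   `start`, `end`, `length`, `dest_chr`, `dest_pos`, `derived_name`,
#'   `derived_start`, `derived_end`), and `segments` (the segment map both
#'   the derived sequences and the ideal alignments are built from).
#' @export
implant_events <- function(truth, cfg) {
  set.seed(cfg$seed + 1L)
  lens <- cfg$chromosome_lengths
  chrs <- names(lens)
  events <- sample_event_sizes(cfg)
  n <- nrow(events)
  if (n > 0) {
    events$id <- sprintf("ev%03d", seq_len(n))
    events$chr <- chrs[sample.int(length(chrs), n, replace = TRUE,
                                  prob = lens)]
    events$start <- NA_real_
    events$end <- NA_real_
    events$dest_chr <- NA_character_
    events$dest_pos <- NA_real_

    ## occupied windows (event bodies and insertion anchors) per chromosome
    occupied <- stats::setNames(
      rep(list(data.frame(start = numeric(0), end = numeric(0))), length(chrs)),
      chrs)
    margin <- cfg$event_margin
    claim <- function(chr, size, extra_ok = NULL) {
      len <- lens[[chr]]
      for (try in seq_len(5000)) {
        occ <- occupied[[chr]]
        s <- round(stats::runif(1, margin, len - margin - size))
        if (s < margin || s + size > len - margin) next
        clear <- nrow(occ) == 0 ||
          all(s + size + margin <= occ$start | s >= occ$end + margin)
        if (clear && (is.null(extra_ok) || extra_ok(s))) {
          occupied[[chr]] <<- rbind(occ, data.frame(start = s, end = s + size))
          return(s)
        }
      }
      stop("chromosome ", chr, " too small to place a ", size,
           " bp event without overlap", call. = FALSE)
    }
    ## 1. claim every source window, so relocation anchors can see them all
    for (i in seq_len(n)) {
      events$start[i] <- claim(events$chr[i], events$length[i])
      events$end[i] <- events$start[i] + events$length[i]
    }
    ## 2. translocation insertion anchors on a different chromosome
    for (i in which(events$type == "translocation")) {
      events$dest_chr[i] <- sample(setdiff(chrs, events$chr[i]), 1)
      events$dest_pos[i] <- claim(events$dest_chr[i], 0)
    }
    ## 3. relocation anchors: the aligned residue between the anchor and the
    ## source window (excised windows removed) must exceed the relocated
    ## segment, so the collinear backbone keeps the flank and marks the
    ## relocated copy out of order.
    excised <- events[events$type %in% c("translocation", "relocation",
                                         "debris"), , drop = FALSE]
    for (i in which(events$type == "relocation")) {
      chr_i <- events$chr[i]
      w_s <- events$start[i]; w_e <- events$end[i]
      size_i <- events$length[i]
      flank_ok <- function(a) {
        lo <- if (a < w_s) a else w_e
        hi <- if (a < w_s) w_s else a
        others <- excised[excised$chr == chr_i & excised$id != events$id[i], ,
                          drop = FALSE]
        cut_bp <- sum(pmax(0, pmin(others$end, hi) - pmax(others$start, lo)))
        (hi - lo) - cut_bp > size_i + margin
      }
      events$dest_chr[i] <- chr_i
      events$dest_pos[i] <- claim(chr_i, 0, extra_ok = flank_ok)
    }
  } else {
    events <- data.frame(type = character(0), length = numeric(0),
                         id = character(0), chr = character(0),
                         start = numeric(0), end = numeric(0),
                         dest_chr = character(0), dest_pos = numeric(0))
  }

  segments <- build_segment_map(events, lens)
  derived <- realize_derived(segments, truth$genome, cfg$gap_run_len)
  events <- locate_derived_coords(events, segments, cfg$gap_run_len)
  catalog <- build_catalog(derived, chromosome_names = chrs,
                           x_name = cfg$x_name)
  list(derived = derived, catalog = catalog, events = events,
       segments = segments)
}

#' Ordered segment map of the derived assembly
#'
#' Each derived sequence is an ordered list of truth-genome windows
#' (`src_chr`, `src_start`, `src_end`, `strand`) tagged with the category a
#' correct classification should recover. Both the derived FASTA and the
#' ideal alignments are realized from this map.
#' @keywords internal
build_segment_map <- function(events, lens) {
  chrs <- names(lens)
  seg <- function(derived_name, src_chr, src_start, src_end, strand,
                  category, event_id) {
    data.frame(derived_name = derived_name, src_chr = src_chr,
               src_start = src_start, src_end = src_end, strand = strand,
               category = category, event_id = event_id,
               stringsAsFactors = FALSE)
  }
  out <- list()
  for (chr in chrs) {
    ev_here <- events[events$chr == chr & !is.na(events$start), ,
                      drop = FALSE]
    ins_here <- events[!is.na(events$dest_chr) & events$dest_chr == chr, ,
                       drop = FALSE]
    cuts <- sort(unique(c(0, lens[[chr]], ev_here$start, ev_here$end,
                          ins_here$dest_pos)))
    pieces <- list()
    for (k in seq_len(length(cuts) - 1)) {
      s <- cuts[k]; e <- cuts[k + 1]
      ## insertions anchored at this cut come first
      anchored <- ins_here[ins_here$dest_pos == s, , drop = FALSE]
      for (j in seq_len(nrow(anchored))) {
        pieces[[length(pieces) + 1]] <- seg(
          chr, anchored$chr[j], anchored$start[j], anchored$end[j], "+",
          anchored$type[j], anchored$id[j])
      }
      inside <- ev_here[ev_here$start <= s & ev_here$end >= e, , drop = FALSE]
      if (nrow(inside) == 0) {
        pieces[[length(pieces) + 1]] <- seg(chr, chr, s, e, "+", "congruent",
                                            NA_character_)
      } else if (inside$type[1] == "inversion") {
        pieces[[length(pieces) + 1]] <- seg(chr, chr, s, e, "-", "inversion",
                                            inside$id[1])
      }
      ## translocation/relocation/debris source windows are excised here
    }
    out[[chr]] <- do.call(rbind, pieces)
  }
  ## debris scaffolds
  deb <- events[events$type == "debris" & !is.na(events$start), ,
                drop = FALSE]
  for (j in seq_len(nrow(deb))) {
    out[[length(out) + 1]] <- seg(
      sprintf("debris_%03d", j), deb$chr[j], deb$start[j], deb$end[j], "+",
      "debris", deb$id[j])
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' @keywords internal
realize_derived <- function(segments, genome, gap_run_len) {
  truth_chr <- as.character(genome)
  derived_names <- unique(segments$derived_name)
  gap <- strrep("N", gap_run_len)
  seqs <- vapply(derived_names, function(nm) {
    sub <- segments[segments$derived_name == nm, , drop = FALSE]
    parts <- vapply(seq_len(nrow(sub)), function(k) {
      s <- substr(truth_chr[[sub$src_chr[k]]], sub$src_start[k] + 1,
                  sub$src_end[k])
      if (sub$strand[k] == "-") {
        s <- as.character(Biostrings::reverseComplement(
          Biostrings::DNAString(s)))
      }
      s
    }, character(1))
    paste(parts, collapse = gap)
  }, character(1))
  Biostrings::DNAStringSet(stats::setNames(seqs, derived_names))
}

#' Query coordinates of every segment in its derived sequence
#' @keywords internal
segment_query_coords <- function(segments, gap_run_len) {
  segments$q_start <- NA_real_
  segments$q_end <- NA_real_
  segments$q_seq_len <- NA_real_
  for (nm in unique(segments$derived_name)) {
    idx <- which(segments$derived_name == nm)
    w <- segments$src_end[idx] - segments$src_start[idx]
    starts <- cumsum(c(0, utils::head(w + gap_run_len, -1)))
    segments$q_start[idx] <- starts
    segments$q_end[idx] <- starts + w
    segments$q_seq_len[idx] <- sum(w) + gap_run_len * (length(idx) - 1)
  }
  segments
}

#' @keywords internal
locate_derived_coords <- function(events, segments, gap_run_len) {
  events$derived_name <- rep(NA_character_, nrow(events))
  events$derived_start <- rep(NA_real_, nrow(events))
  events$derived_end <- rep(NA_real_, nrow(events))
  if (nrow(events) == 0) return(events)
  sq <- segment_query_coords(segments, gap_run_len)
  for (i in seq_len(nrow(events))) {
    k <- which(sq$event_id == events$id[i])[1]
    if (!is.na(k)) {
      events$derived_name[i] <- sq$derived_name[k]
      events$derived_start[i] <- sq$q_start[k]
      events$derived_end[i] <- sq$q_end[k]
    }
  }
  events
}

#' Emit idealized PAF alignments between derived and truth assemblies
#'
#' Computes exact alignment blocks directly from the implant edit history:
#' one block per segment, with correct strand and coordinates, residue
#' matches equal to the block length, and mapQ 60. Junction gap runs are
#' unaligned, as a real aligner would leave them. With
#' `fragmentation_rate > 0`, blocks are additionally split at Poisson-random
#' breakpoints — emulating alignment fragmentation — without changing the
#' covered bp. The returned table carries `truth_category` and `event_id`
#' provenance columns (ignored by the classifier, used for recovery
#' scoring); [write_paf()] drops them.
#'
#' @param sim output of [implant_events()].
#' @param truth output of [generate_truth()].
#' @param cfg the [simulation_config()].
#' @param noise apply fragmentation noise (default `FALSE`).
#' @return alignment-block table (query = derived assembly, target = truth).
#' @export
emit_ideal_paf <- function(sim, truth, cfg, noise = FALSE) {
  set.seed(cfg$seed + 2L)
  sq <- segment_query_coords(sim$segments, cfg$gap_run_len)
  t_len <- stats::setNames(truth$catalog$sequences$length,
                           truth$catalog$sequences$name)
  rows <- lapply(seq_len(nrow(sq)), function(k) {
    len <- sq$src_end[k] - sq$src_start[k]
    offs <- c(0, len)
    if (noise && cfg$fragmentation_rate > 0) {
      nb <- stats::rpois(1, cfg$fragmentation_rate * len)
      if (nb > 0) {
        offs <- sort(unique(c(0, sample.int(len - 1, min(nb, len - 1)), len)))
      }
    }
    m <- length(offs) - 1
    o1 <- offs[-length(offs)]
    o2 <- offs[-1]
    if (sq$strand[k] == "+") {
      ts <- sq$src_start[k] + o1
      te <- sq$src_start[k] + o2
    } else {
      ts <- sq$src_end[k] - o2
      te <- sq$src_end[k] - o1
    }
    data.frame(
      query_name = sq$derived_name[k],
      query_seq_len = sq$q_seq_len[k],
      query_start = sq$q_start[k] + o1,
      query_end = sq$q_start[k] + o2,
      strand = sq$strand[k],
      target_name = sq$src_chr[k],
      target_seq_len = as.numeric(t_len[sq$src_chr[k]]),
      target_start = ts,
      target_end = te,
      residue_matches = o2 - o1,
      block_len = o2 - o1,
      mapq = 60,
      truth_category = sq$category[k],
      event_id = sq$event_id[k],
      stringsAsFactors = FALSE
    )
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  validate_blocks(out)
  out
}

#' Simulate a complete assembly pair
#'
#' Convenience wrapper running [generate_truth()], [implant_events()] and
#' [emit_ideal_paf()] under one configuration.
#'
#' @param cfg a [simulation_config()].
#' @param noise apply fragmentation noise to the ideal alignments.
#' @return list with `truth`, `derived` (implant output), and `paf`.
#' @export
simulate_assembly_pair <- function(cfg = simulation_config(), noise = FALSE) {
  truth <- generate_truth(cfg)
  derived <- implant_events(truth, cfg)
  paf <- emit_ideal_paf(derived, truth, cfg, noise = noise)
  list(truth = truth, derived = derived, paf = paf)
}

#' Write all simulator artifacts to a directory
#'
#' Produces `truth.fa`, `derived.fa`, `repeats.bed`, `truth_events.tsv` and
#' `ideal.paf` under `outdir`.
#'
#' @param sim output of [simulate_assembly_pair()].
#' @param outdir output directory (created if absent).
#' @return invisible `outdir`.
#' @export
write_simulation <- function(sim, outdir) {
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  Biostrings::writeXStringSet(sim$truth$genome, file.path(outdir, "truth.fa"))
  Biostrings::writeXStringSet(sim$derived$derived,
                              file.path(outdir, "derived.fa"))
  iv <- sim$truth$repeats$intervals
  utils::write.table(iv[, c("name", "start", "end")],
                     file.path(outdir, "repeats.bed"), sep = "\t",
                     quote = FALSE, row.names = FALSE, col.names = FALSE)
  utils::write.table(sim$derived$events, file.path(outdir, "truth_events.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  write_paf(sim$paf, file.path(outdir, "ideal.paf"))
  invisible(outdir)
}

#' Per-category recovery scores against simulator truth
#'
#' Joins classification labels with the provenance the simulator attached to
#' each emitted block and reports bp-level precision and recall per
#' category. Recall denominators are the truth bp per category over all
#' emitted blocks (so bp lost to filtering counts against recall);
#' precision denominators are the bp the classifier assigned to the
#' category.
#'
#' @param labeled output of [classify_blocks()] run on blocks carrying the
#'   simulator's `truth_category` column.
#' @param paf the full emitted alignment table (pre-filtering), for truth
#'   denominators.
#' @return data.frame with columns `category`, `truth_bp`, `labeled_bp`,
#'   `true_positive_bp`, `precision`, `recall`.
#' @export
score_recovery <- function(labeled, paf) {
  stopifnot("truth_category" %in% names(labeled),
            "truth_category" %in% names(paf))
  cats <- ALL_LABELS
  span_l <- query_span(labeled)
  span_p <- query_span(paf)
  res <- lapply(cats, function(cc) {
    truth_bp <- sum(span_p[paf$truth_category == cc])
    labeled_bp <- sum(span_l[labeled$label == cc])
    tp <- sum(span_l[labeled$label == cc & labeled$truth_category == cc])
    data.frame(category = cc, truth_bp = truth_bp, labeled_bp = labeled_bp,
               true_positive_bp = tp,
               precision = ifelse(labeled_bp > 0, tp / labeled_bp, NA_real_),
               recall = ifelse(truth_bp > 0, tp / truth_bp, NA_real_))
  })
  do.call(rbind, res)
}

#' Simulate per-chromosome discrepancy/repeat profiles with a planted signal
#'
#' Generates the profile table [regress()] consumes directly, without
#' sequence-level simulation: autosome repeat densities drawn uniformly, an
#' X-like chromosome at an elevated density, and discrepancy percentages
#' following a planted linear dependence on repeat density plus Gaussian
#' noise. With `x_only_signal = TRUE` the autosomes are flat (noise around
#' the intercept) and only the X point carries the planted relationship —
#' the situation in which an apparent genome-wide association hinges
#' entirely on the X chromosome.
#'
#' @param n_chromosomes total chromosomes including the X.
#' @param slope,intercept planted linear relationship (percent per percent).
#' @param noise_sd Gaussian noise on discrepancy %.
#' @param repeat_pct_range autosome repeat density range.
#' @param x_repeat_pct X repeat density.
#' @param x_only_signal plant the signal only in the X point.
#' @param seed integer seed.
#' @return data.frame compatible with [regress()].
#' @export
simulate_chromosome_profiles <- function(n_chromosomes = 22,
                                         slope = 0.4,
                                         intercept = 1,
                                         noise_sd = 1,
                                         repeat_pct_range = c(30, 45),
                                         x_repeat_pct = 55,
                                         x_only_signal = FALSE,
                                         seed = 1) {
  set.seed(seed)
  n_auto <- n_chromosomes - 1
  rep_pct <- c(stats::runif(n_auto, repeat_pct_range[1], repeat_pct_range[2]),
               x_repeat_pct)
  mu <- if (x_only_signal) {
    c(rep(intercept, n_auto), intercept + slope * x_repeat_pct)
  } else {
    intercept + slope * rep_pct
  }
  disc <- pmax(0, mu + stats::rnorm(n_chromosomes, 0, noise_sd))
  lens <- round(stats::runif(n_chromosomes, 5e7, 2e8))
  data.frame(
    chromosome = c(sprintf("chr%d", seq_len(n_auto)), "chrX"),
    length = lens,
    discrepancy_bp = round(disc / 100 * lens),
    discrepancy_pct = disc,
    repeat_bp = round(rep_pct / 100 * lens),
    repeat_pct = rep_pct,
    is_x = c(rep(FALSE, n_auto), TRUE),
    stringsAsFactors = FALSE
  )
}
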