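test_that("published category bp reproduce the printed percentages at their
           printed precision", {
  tabs <- monodontid_discrepancy_tables()
  pct <- function(nm, cat) {
    t <- tabs[[nm]]
    t$pct[t$category == cat]
  }
  expect_equal(round_half_up(pct("Mm_Damas_", "inversion"), 1), 5.3)
  expect_equal(round_half_up(pct("Mm_Damas_", "debris"), 1), 2.5)
  expect_equal(round_half_up(pct("Dl_Jones_", "inversion"), 2), 1.25)
  expect_equal(round_half_up(pct("Dl_zoo_", "congruent"), 1), 92.9)
  expect_equal(round_half_up(pct("Dl_3_", "inversion"), 1), 1.8)
  expect_equal(round_half_up(pct("Dl_4_", "inversion"), 1), 1.7)
})

test_that("headline total discrepancy percentages are recovered", {
  tabs <- monodontid_discrepancy_tables()
  expect_equal(total_discrepancy(tabs$Mm_Damas_), 8.2)
  totals <- vapply(tabs[c("Dl_Jones_", "Dl_zoo_", "Dl_3_", "Dl_4_")],
                   total_discrepancy, numeric(1))
  expect_equal(max(totals), 3.7)  # most discrepant beluga comparison
  expect_equal(min(totals), 2.2)  # least discrepant beluga comparison
  empty <- discrepancy_table(c(congruent = 100))
  expect_equal(total_discrepancy(empty), 0)
})

test_that("category percentages always sum to 100 and bp partition the
           evaluated total", {
  for (tab in monodontid_discrepancy_tables()) {
    expect_equal(sum(tab$bp), attr(tab, "evaluated_total"))
    expect_equal(round_half_up(sum(tab$pct), 1), 100.0)
  }
  set.seed(909)
  for (rep in 1:20) {
    bp <- stats::setNames(sample.int(1e6, 6),
                          c("debris", "translocation", "inversion",
                            "relocation", "unassessed", "congruent"))
    tab <- discrepancy_table(bp)
    expect_equal(sum(tab$bp), sum(bp))
    expect_equal(sum(tab$pct), 100.0)
    # independent re-summation of the discrepancy total
    expect_equal(
      total_discrepancy(tab, digits = 6),
      round_half_up(100 * sum(bp[c("debris", "translocation", "inversion",
                                   "relocation")]) / sum(bp), 6))
  }
})

test_that("tally partitions discarded, stacked and labeled bp and is
           invariant to block order and block splitting", {
  set.seed(111)
  b <- random_blocks(200)
  out <- apply_filters(b)
  qc <- toy_catalog(paste0("q", 1:4), rep(3e6, 4))
  rc <- toy_catalog(paste0("t", 1:4), rep(3e6, 4))
  lab <- classify_blocks(out$retained, qc, rc)
  tab <- tally(lab, out)
  spans <- function(d) sum(d$query_end - d$query_start)
  expect_equal(attr(tab, "evaluated_total"),
               spans(out$retained) + spans(out$discarded) +
                 spans(out$stacked))
  expect_equal(tab$bp[tab$category == "unassessed"],
               spans(out$discarded) + spans(out$stacked))
  expect_equal(sum(tab$bp), attr(tab, "evaluated_total"))

  # order invariance
  perm <- lab[sample.int(nrow(lab)), ]
  expect_equal(tally(perm, out)$bp, tab$bp)

  # splitting a labeled block in two conserves the tally
  split_one <- lab
  i <- which.max(split_one$query_end - split_one$query_start)
  mid <- floor((split_one$query_start[i] + split_one$query_end[i]) / 2)
  piece <- split_one[i, ]
  piece$query_start <- mid
  split_one$query_end[i] <- mid
  expect_equal(tally(rbind(split_one, piece), out)$bp, tab$bp)
})

test_that("the assembly denominator folds the unaligned remainder into
           unassessed", {
  qcat <- toy_catalog("q1", 1e6)
  rcat <- toy_catalog("t1", 1e6)
  b <- blk("q1", 0, 600000, "t1", 0, 600000)
  out <- apply_filters(b)
  lab <- classify_blocks(out$retained, qcat, rcat)
  tab <- tally(lab, out, ref_catalog = rcat, denominator = "assembly")
  expect_equal(attr(tab, "evaluated_total"), 1e6)
  expect_equal(tab$bp[tab$category == "unassessed"], 4e5)
  expect_equal(sum(tab$bp), 1e6)
})

test_that("zero evaluated total is an error", {
  expect_error(discrepancy_table(c(congruent = 0)), "positive")
})

test_that("chromosome profiles project discrepancy bp onto targets and
           compute repeat density", {
  rcat <- toy_catalog(c("t1", "t2"), c(1e6, 1e6), x = "t2")
  track <- repeat_track_from_intervals(
    data.frame(name = "t1", start = 0, end = 5e5), rcat)
  lab <- rbind(blk("q1", 0, 1e5, "t1", 0, 1e5),
               blk("q1", 2e5, 25e4, "t2", 0, 5e4))
  lab$label <- c("inversion", "congruent")
  lab$evidence <- ""
  prof <- chromosome_profiles(lab, rcat, track)
  expect_equal(prof$discrepancy_bp, c(1e5, 0))
  expect_equal(prof$discrepancy_pct, c(10, 0))
  expect_equal(prof$repeat_pct, c(50, 0))
  expect_equal(prof$is_x, c(FALSE, TRUE))
})

test_that("per-chromosome discrepancy bp equals a per-base mask oracle", {
  set.seed(222)
  rcat <- toy_catalog(c("t1", "t2"), c(5e4, 5e4))
  track <- repeat_track()
  n <- 100
  ts <- floor(runif(n, 0, 4e4))
  span <- 1 + floor(runif(n, 0, 5000))
  lab <- alignment_blocks(
    query_name = "q1", query_seq_len = 1e6,
    query_start = seq_len(n) * 6000, query_end = seq_len(n) * 6000 + span,
    strand = "+", target_name = sample(c("t1", "t2"), n, replace = TRUE),
    target_seq_len = 5e4, target_start = ts,
    target_end = pmin(ts + span, 5e4),
    residue_matches = span, block_len = span, mapq = 60)
  lab$label <- sample(c("inversion", "relocation", "congruent"), n,
                      replace = TRUE)
  lab$evidence <- ""
  prof <- chromosome_profiles(lab, rcat, track)
  for (t in c("t1", "t2")) {
    keep <- lab$target_name == t &
      lab$label %in% c("inversion", "relocation")
    want <- sum((lab$query_end - lab$query_start)[keep])
    expect_equal(prof$discrepancy_bp[prof$chromosome == t], want)
  }
})

test_that("OLS matches the closed-form normal equations to 1e-10", {
  set.seed(333)
  for (rep in 1:20) {
    n <- sample(5:30, 1)
    x <- runif(n, 20, 60)
    y <- pmax(0, 1 + 0.3 * x + rnorm(n))
    prof <- data.frame(chromosome = paste0("c", 1:n), length = 1e6,
                       discrepancy_bp = 0, discrepancy_pct = y,
                       repeat_bp = 0, repeat_pct = x, is_x = FALSE)
    fit <- regress(prof)
    slope <- sum((x - mean(x)) * (y - mean(y))) / sum((x - mean(x))^2)
    intercept <- mean(y) - slope * mean(x)
    yhat <- intercept + slope * x
    r2 <- 1 - sum((y - yhat)^2) / sum((y - mean(y))^2)
    expect_equal(fit$slope, slope, tolerance = 1e-10)
    expect_equal(fit$intercept, intercept, tolerance = 1e-10)
    expect_equal(fit$r_squared, r2, tolerance = 1e-10)
    # shuffling the points changes nothing
    fit2 <- regress(prof[sample.int(n), ])
    expect_equal(fit2$slope, fit$slope)
  }
})

test_that("regression degenerate and boundary cases behave as specified", {
  prof <- data.frame(chromosome = c("a", "b", "c"), length = 1e6,
                     discrepancy_bp = 0,
                     discrepancy_pct = c(1, 2, 3),
                     repeat_bp = 0, repeat_pct = c(10, 20, 30),
                     is_x = FALSE)
  # exact fits make lm's t-statistics degenerate, which it warns about
  fit <- suppressWarnings(regress(prof))
  expect_equal(fit$r_squared, 1.0)
  flat <- prof
  flat$discrepancy_pct <- 5
  expect_equal(suppressWarnings(regress(flat))$slope, 0)
  expect_error(regress(prof[1:2, ]), "at least 3")
  novar <- prof
  novar$repeat_pct <- 10
  expect_error(regress(novar), "zero variance")
  # Bonferroni: alpha scales with the number of comparisons
  expect_equal(suppressWarnings(regress(prof, n_comparisons = 5))$alpha_corrected,
               0.01)
})

test_that("excluding the X re-fits rather than reusing cached results", {
  prof <- simulate_chromosome_profiles(n_chromosomes = 10, x_only_signal = TRUE,
                                       slope = 0.4, noise_sd = 0.3, seed = 4)
  with_x <- regress(prof)
  without_x <- regress(prof, exclude_x = TRUE)
  expect_equal(without_x$n_chromosomes, 9)
  expect_true(without_x$r_squared < with_x$r_squared)
})
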