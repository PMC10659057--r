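test_that("dominant target is the bp arg-max with deterministic ties", {
  b <- rbind(
    blk("q_chr1", 0, 8000, "t_chr1", 0, 8000),
    blk("q_chr1", 10000, 11000, "t_chr2", 0, 1000)
  )
  dom <- dominant_target(b, "q_chr1")
  expect_equal(dom$target, "t_chr1")
  expect_equal(dom$support_bp, 8000)
  # exact tie -> lexicographically smaller target
  tie <- rbind(blk("q", 0, 1000, "tB", 0, 1000),
               blk("q", 2000, 3000, "tA", 0, 1000))
  expect_equal(dominant_target(tie, "q")$target, "tA")
  expect_error(dominant_target(b, "missing"), "no retained blocks")
})

test_that("dominant target equals an exhaustive per-target summation oracle", {
  set.seed(404)
  for (rep in 1:20) {
    b <- random_blocks(100)
    for (q in unique(b$query_name)) {
      sub <- b[b$query_name == q, ]
      sums <- tapply(sub$query_end - sub$query_start, sub$target_name, sum)
      best <- max(sums)
      expect_equal(dominant_target(b, q)$target,
                   min(names(sums)[sums == best]))
      expect_equal(dominant_target(b, q)$support_bp, unname(best))
    }
  }
})

test_that("dominant strand is the bp arg-max with forward tie-break", {
  b <- rbind(blk("q", 0, 10000, "t", 0, 10000, "+"),
             blk("q", 20000, 22000, "t", 20000, 22000, "-"))
  expect_equal(dominant_strand(b, "t"), "+")
  tie <- rbind(blk("q", 0, 1000, "t", 0, 1000, "-"),
               blk("q", 2000, 3000, "t", 2000, 3000, "+"))
  expect_equal(dominant_strand(tie, "t"), "+")
  set.seed(505)
  for (rep in 1:20) {
    b <- random_blocks(80)
    for (t in unique(b$target_name)) {
      sub <- b[b$target_name == t, ]
      span <- sub$query_end - sub$query_start
      fwd <- sum(span[sub$strand == "+"])
      rev <- sum(span[sub$strand == "-"])
      expect_equal(dominant_strand(b, t), if (fwd >= rev) "+" else "-")
    }
  }
})

test_that("collinear blocks form a full backbone; a small displaced block
           is excluded", {
  collinear <- do.call(rbind, lapply(0:4, function(i) {
    blk("q", i * 10000, i * 10000 + 10000, "t", i * 10000, i * 10000 + 10000)
  }))
  expect_true(all(backbone(collinear)))
  displaced <- rbind(collinear,
                     blk("q", 60000, 62000, "t", 5000, 7000))
  member <- backbone(displaced)
  expect_equal(member, c(rep(TRUE, 5), FALSE))
})

test_that("backbone weight equals the exhaustive enumeration oracle", {
  set.seed(606)
  for (rep in 1:30) {
    n <- sample(2:12, 1)
    qs <- sort(sample.int(1e5, n))
    span <- 1 + sample.int(5000, n)
    ts <- sample.int(1e5, n)
    b <- alignment_blocks(
      query_name = "q", query_seq_len = 2e5, query_start = qs,
      query_end = qs + span, strand = "+", target_name = "t",
      target_seq_len = 2e6, target_start = ts, target_end = ts + span,
      residue_matches = span, block_len = span, mapq = 60
    )
    member <- backbone(b)
    got <- sum((b$query_end - b$query_start)[member])
    # oracle: enumerate every subset, in query order
    ord <- order(b$query_start)
    want <- exhaustive_increasing_weight(b$target_start[ord],
                                         (b$query_end - b$query_start)[ord])
    expect_equal(got, want)
    # backbone members must be strictly increasing in query order
    m <- b[member, ]
    m <- m[order(m$query_start), ]
    if (nrow(m) > 1) expect_true(all(diff(m$target_start) > 0))
  }
})

test_that("precedence: a block failing both target and strand criteria is a
           translocation, not an inversion", {
  qcat <- toy_catalog(c("q1", "q2"), c(1e6, 1e6))
  rcat <- toy_catalog(c("t1", "t2"), c(1e6, 1e6))
  b <- rbind(
    blk("q1", 0, 100000, "t1", 0, 100000, "+"),
    blk("q1", 200000, 210000, "t2", 0, 10000, "-"),  # wrong target AND strand
    blk("q2", 0, 100000, "t2", 100000, 200000, "+")
  )
  lab <- classify_blocks(b, qcat, rcat)
  expect_equal(lab$label, c("congruent", "translocation", "congruent"))
  expect_match(lab$evidence[2], "dominant target")
})

test_that("debris outranks everything and respects the debris_side switch", {
  qcat <- toy_catalog(c("q1", "frag"), c(1e6, 50000),
                      chromosomes = "q1")
  rcat <- toy_catalog(c("t1", "junk"), c(1e6, 40000),
                      chromosomes = "t1")
  b <- rbind(
    blk("frag", 0, 30000, "t1", 500000, 530000, "-", qlen = 50000),
    blk("q1", 0, 100000, "t1", 0, 100000),
    blk("q1", 200000, 220000, "junk", 0, 20000, tlen = 40000)
  )
  lab <- classify_blocks(b, qcat, rcat)
  # query-side debris wins over the inversion criterion it would also meet
  expect_equal(lab$label[1], "debris")
  # reference-side debris only counts under the switch
  expect_equal(lab$label[3], "translocation")
  lab_both <- classify_blocks(b, qcat, rcat, debris_side = "both")
  expect_equal(lab_both$label[3], "debris")
  lab_ref <- classify_blocks(b, qcat, rcat, debris_side = "reference")
  expect_equal(lab_ref$label[1], "inversion")
  expect_equal(lab_ref$label[3], "debris")
})

test_that("debris-to-debris alignments fall through to congruent when
           collinear", {
  qcat <- toy_catalog(c("q1", "fragQ"), c(1e6, 50000), chromosomes = "q1")
  rcat <- toy_catalog(c("t1", "fragT"), c(1e6, 60000), chromosomes = "t1")
  b <- rbind(blk("q1", 0, 100000, "t1", 0, 100000),
             blk("fragQ", 0, 40000, "fragT", 0, 40000, qlen = 50000,
                 tlen = 60000))
  lab <- classify_blocks(b, qcat, rcat)
  expect_equal(lab$label, c("congruent", "congruent"))
})

test_that("an ideal self-alignment is entirely congruent and label sets are
           invariant to input order", {
  qcat <- toy_catalog(c("c1", "c2"), c(5e5, 4e5))
  b <- rbind(blk("c1", 0, 5e5, "c1", 0, 5e5, qlen = 5e5, tlen = 5e5),
             blk("c2", 0, 4e5, "c2", 0, 4e5, qlen = 4e5, tlen = 4e5))
  lab <- classify_blocks(b, qcat, qcat)
  expect_true(all(lab$label == "congruent"))

  set.seed(707)
  rb <- random_blocks(120)
  out <- apply_filters(rb)
  qc <- toy_catalog(paste0("q", 1:4), rep(3e6, 4))
  rc <- toy_catalog(paste0("t", 1:4), rep(3e6, 4))
  lab1 <- classify_blocks(out$retained, qc, rc)
  perm <- out$retained[sample.int(nrow(out$retained)), ]
  lab2 <- classify_blocks(perm, qc, rc)
  key <- function(d) {
    d <- d[order(d$query_name, d$query_start, d$target_name, d$target_start), ]
    paste(d$query_name, d$query_start, d$label)
  }
  expect_equal(key(lab1), key(lab2))
  expect_true(all(nchar(lab1$evidence) > 0))
})

test_that("monotone sanity: no reverse blocks means no inversions; untouched
           order means no relocations", {
  set.seed(808)
  b <- random_blocks(150)
  b$strand <- "+"
  out <- apply_filters(b)
  qc <- toy_catalog(paste0("q", 1:4), rep(3e6, 4))
  rc <- toy_catalog(paste0("t", 1:4), rep(3e6, 4))
  lab <- classify_blocks(out$retained, qc, rc)
  expect_false(any(lab$label == "inversion"))

  collinear <- do.call(rbind, lapply(0:9, function(i) {
    blk("q1", i * 10000, i * 10000 + 9000, "t1", i * 10000, i * 10000 + 9000)
  }))
  lab2 <- classify_blocks(collinear, toy_catalog("q1", 1e6),
                          toy_catalog("t1", 1e6))
  expect_false(any(lab2$label == "relocation"))
})

test_that("a catalog missing a sequence named in the blocks is an error", {
  b <- blk("q1", 0, 1000, "t1", 0, 1000)
  expect_error(
    classify_blocks(b, toy_catalog("other", 1e6), toy_catalog("t1", 1e6)),
    "q1")
  expect_error(
    classify_blocks(b, toy_catalog("q1", 1e6), toy_catalog("other", 1e6)),
    "t1")
})
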