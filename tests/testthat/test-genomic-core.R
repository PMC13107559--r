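test_that("canonicalize_loops orders anchors, is idempotent, rejects trans", {
  raw <- data.frame(id = "a", chrom = "chr1", start1 = 100, end1 = 200,
                    start2 = 50, end2 = 90)
  can <- canonicalize_loops(raw)
  expect_equal(c(can$start1, can$end1, can$start2, can$end2),
               c(50, 90, 100, 200))
  expect_identical(canonicalize_loops(can), can)
  expect_identical(can$id, "a")

  trans <- data.frame(id = "t", chrom = "chr1", chrom2 = "chr2",
                      start1 = 0, end1 = 10, start2 = 100, end2 = 110)
  expect_error(canonicalize_loops(trans), "trans interaction")
  expect_error(canonicalize_loops(
    data.frame(id = "o", chrom = "chr1", start1 = 0, end1 = 100,
               start2 = 50, end2 = 150)), "overlap")
})

test_that("loop_span modes and degenerate anchors", {
  l <- mk_loop("x", 0, 100, 900, 1000)
  expect_equal(loop_span(l, "outer")[, c("start", "end")],
               data.frame(start = 0, end = 1000))
  expect_equal(loop_span(l, "midpoint")[, c("start", "end")],
               data.frame(start = 50, end = 950))
  d <- mk_loop("d", 10, 11, 500, 501)
  expect_equal(loop_span(d, "midpoint")$start, 10)
  expect_equal(loop_span(d, "midpoint")$end, 500)
})

test_that("intervals_overlap honors half-open convention, slack, chrom", {
  a <- mk_intervals(0, 10); b <- mk_intervals(10, 20)
  expect_false(intervals_overlap(a, b, slack = 0))
  expect_true(intervals_overlap(a, b, slack = 1))
  expect_true(intervals_overlap(b, a, slack = 1))
  b2 <- mk_intervals(10, 20, chrom = "chr2")
  expect_false(intervals_overlap(a, b2, slack = 5))
  expect_error(intervals_overlap(a, b, slack = -1), "slack")
})

test_that("union_coverage: examples, idempotence, bitmap-oracle equality", {
  genome <- c(chr1 = 1000)
  two <- mk_intervals(c(100, 500), c(200, 600))
  expect_equal(union_coverage(two, genome), 0.2)
  dup <- mk_intervals(c(100, 100), c(200, 200))
  expect_equal(union_coverage(dup, genome),
               union_coverage(dup[1, ], genome))
  set.seed(11)
  for (rep in 1:5) {
    g <- c(chr1 = 10000)
    s <- sort(sample(0:9500, 50))
    spans <- mk_intervals(s, s + sample(1:500, 50, replace = TRUE))
    expect_identical(union_coverage(spans, g), oracle_union_coverage(spans, g))
  }
  expect_warning(union_coverage(mk_intervals(900, 1200), genome), "clipped")
})

test_that("an interval of length L covers exactly L bases (half-open)", {
  set.seed(12)
  for (L in sample(1:1000, 10)) {
    g <- c(chr1 = 5000)
    start <- sample(0:(5000 - L), 1)
    expect_equal(oracle_union_coverage(mk_intervals(start, start + L), g) * 5000,
                 L)
    expect_equal(union_coverage(mk_intervals(start, start + L), g) * 5000, L)
  }
})

test_that("nearest_neighbor_distance: arithmetic, singles, brute force", {
  s <- mk_intervals(c(50, 250, 950), c(150, 350, 1050))  # mids 100, 300, 1000
  expect_equal(nearest_neighbor_distance(s), c(200, 200, 700))
  one <- mk_intervals(10, 20)
  expect_true(is.na(nearest_neighbor_distance(one)))
  set.seed(13)
  pos <- sample(0:1e6, 500)
  sites <- mk_intervals(pos, pos + 100)
  mids <- interval_midpoints(sites)
  brute <- sapply(seq_along(mids), function(i) min(abs(mids[-i] - mids[i])))
  expect_equal(nearest_neighbor_distance(sites), brute)
})

test_that("BEDPE and BED round-trips are lossless; bad lines are located", {
  set.seed(14)
  x <- random_loops(25)
  f <- withr::local_tempfile(fileext = ".bedpe")
  write_bedpe(x, f)
  y <- read_bedpe(f, conditions = c("untreated", "IAA"))
  rownames(x) <- NULL
  expect_equal(y, x)
  # read-write-read stability
  f2 <- withr::local_tempfile(fileext = ".bedpe")
  write_bedpe(y, f2)
  expect_equal(read_bedpe(f2, conditions = c("untreated", "IAA")), y)

  bed <- mk_intervals(c(0, 500), c(100, 900),
                      name = c("p1", "p2"), score = c(1.5, 2),
                      strand = c("+", "-"))
  fb <- withr::local_tempfile(fileext = ".bed")
  write_bed(bed, fb)
  expect_equal(read_bed(fb), bed)

  bad <- withr::local_tempfile()
  writeLines(c("# hdr", "chr1\t100\t50\tx\t0\t+"), bad)
  expect_error(read_bed(bad), "line 2")
  bad2 <- withr::local_tempfile()
  writeLines("chr1\t10\t20\tchr1\t5\tnine\tq\t1\t.\t.", bad2)
  expect_error(read_bedpe(bad2), "line 1")
  bad3 <- withr::local_tempfile()
  writeLines("chr1\t10\t20\tchr2\t50\t60\tq\t1\t.\t.", bad3)
  expect_error(read_bedpe(bad3), "trans")
})

test_that("clip_intervals validates genome and drops out-of-range rows", {
  g <- c(chr1 = 100)
  expect_error(clip_intervals(mk_intervals(0, 10, chrom = "chrX"), g),
               "not in genome")
  out <- suppressWarnings(clip_intervals(mk_intervals(c(90, 150), c(120, 160)), g))
  expect_equal(nrow(out), 1)
  expect_equal(out$end, 100)
})
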