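# The CTCF loop used in most examples spans 3,000-7,000 (anchor midpoints);
# anchors are 200 bp wide around the midpoints.
ctcf_example <- function(strength = 1, id = "c1")
  mk_loop(id, 2900, 3100, 6900, 7100, strength = strength)

test_that("relate_pair: contain subtypes pinned by shared-anchor count", {
  c1 <- ctcf_example()
  # anchors coincide with the CTCF anchors -> contain III
  h3 <- mk_loop("h3", 2900, 3100, 6900, 7100)
  r <- relate_pair(h3, c1)
  expect_equal(r$relation, "contain")
  expect_equal(r$contain_subtype, 3L)
  # strict nesting, no shared anchors -> contain I
  h1 <- mk_loop("h1", 1000, 1100, 9000, 9100)
  r1 <- relate_pair(h1, c1)
  expect_equal(r1$relation, "contain")
  expect_equal(r1$contain_subtype, 1L)
  # one shared anchor, other beyond the far edge -> contain II
  h2 <- mk_loop("h2", 2900, 3100, 9000, 9100)
  r2 <- relate_pair(h2, c1)
  expect_equal(r2$relation, "contain")
  expect_equal(r2$contain_subtype, 2L)
  expect_true(r2$shared_left && !r2$shared_right)
})

test_that("relate_pair: cross, inside, neighbor, none", {
  c1 <- ctcf_example()
  expect_equal(relate_pair(mk_loop("x", 3950, 4050, 11950, 12050), c1)$relation,
               "cross")
  expect_equal(relate_pair(mk_loop("i", 3950, 4050, 5950, 6050), c1)$relation,
               "inside")
  # shares the left CTCF anchor, extends away leftwards
  expect_equal(relate_pair(mk_loop("n", 900, 1100, 2900, 3100), c1)$relation,
               "neighbor")
  expect_equal(relate_pair(mk_loop("o", 8000, 8100, 9500, 9600), c1)$relation,
               "none")
  # different chromosomes
  c2 <- mk_loop("c2", 2900, 3100, 6900, 7100, chrom = "chr2")
  expect_equal(relate_pair(mk_loop("t", 3950, 4050, 11950, 12050), c2)$relation,
               "none")
})

test_that("relate_pair agrees with the scalar oracle on random pairs", {
  set.seed(41)
  for (span_mode in c("midpoint", "outer")) for (slack in c(0, 500)) {
    h <- random_loops(120, genome = 1e5, aw = 300, min_gap = 1e3,
                      max_span = 4e4, prefix = "h")
    c <- random_loops(40, genome = 1e5, aw = 300, min_gap = 1e3,
                      max_span = 4e4, prefix = "c")
    for (i in sample(120, 40)) for (j in sample(40, 10)) {
      got <- relate_pair(h[i, ], c[j, ], slack = slack,
                         span_mode = span_mode)
      want <- oracle_relate(h[i, ], c[j, ], slack = slack,
                            span_mode = span_mode)
      want_rel <- sub("_[0-9]$", "", want)
      expect_equal(got$relation, sub("contain_[0-9]", "contain", want_rel),
                   info = paste(span_mode, slack, i, j))
      if (startsWith(want, "contain_"))
        expect_equal(got$contain_subtype,
                     as.integer(sub("contain_", "", want)) + 1L)
    }
  }
})

test_that("classify_topology: examples and combination rule", {
  c1 <- ctcf_example(strength = 5)
  far <- mk_loop("cfar", 502900, 503100, 506900, 507100, strength = 9)
  # no CTCF loop anywhere near -> outside
  lonely <- mk_loop("ho", 100000, 100100, 140000, 140100)
  expect_equal(classify_topology(lonely, c1)$category, "outside")
  # a single contain-III relation -> contain
  h3 <- mk_loop("h3", 2900, 3100, 6900, 7100)
  t3 <- classify_topology(h3, c1)
  expect_equal(t3$category, "contain")
  expect_equal(t3$contain_subtype, 3L)
  # contain (strength 5) + cross (strength 9) -> contain_and_cross
  cc_ctcf <- rbind(c1, mk_loop("c9", 19900, 20100, 39900, 40100,
                               strength = 9))
  hcc <- mk_loop("hcc", 1000, 1100, 29000, 29100)
  tcc <- classify_topology(hcc, cc_ctcf)
  expect_equal(tcc$category, "contain_and_cross")
  expect_equal(tcc$max_contain_strength, 5)
  expect_equal(tcc$max_cross_strength, 9)
})

test_that("indexed classification equals the scalar-oracle double loop", {
  set.seed(42)
  h <- random_loops(200, genome = 2e6, aw = 400, max_span = 2e5,
                    prefix = "h")
  c <- random_loops(50, genome = 2e6, aw = 400, max_span = 2e5,
                    prefix = "c")
  got <- classify_topology(h, c)
  want <- oracle_classify(h, c)
  expect_equal(got$category, want$category)
  expect_equal(got$contain_subtype, want$contain_subtype)
})

test_that("every interaction gets exactly one category (partition)", {
  set.seed(43)
  h <- random_loops(300, genome = 2e6, prefix = "h")
  c <- random_loops(40, genome = 2e6, prefix = "c")
  topo <- classify_topology(h, c)
  expect_equal(nrow(topo), nrow(h))
  expect_true(all(topo$category %in% topology_categories()))
  cd <- category_distribution(topo)
  expect_equal(sum(cd$count), nrow(h))
  expect_equal(sum(cd$percent), 100)
})

test_that("translation invariance of all labels", {
  set.seed(44)
  h <- random_loops(150, genome = 1e6, prefix = "h")
  c <- random_loops(30, genome = 1e6, prefix = "c")
  base <- classify_topology(h, c)
  off <- 123457
  shift <- function(x) {
    x$start1 <- x$start1 + off; x$end1 <- x$end1 + off
    x$start2 <- x$start2 + off; x$end2 <- x$end2 + off
    x
  }
  moved <- classify_topology(shift(h), shift(c))
  expect_equal(moved$category, base$category)
  expect_equal(moved$contain_subtype, base$contain_subtype)
})

test_that("deleting a CTCF loop never creates a new non-outside relation", {
  set.seed(45)
  h <- random_loops(100, genome = 1e6, prefix = "h")
  c <- random_loops(25, genome = 1e6, prefix = "c")
  full <- attr(classify_topology(h, c), "relations")
  drop <- c[c$id != sample(c$id, 1), ]
  reduced <- attr(classify_topology(h, drop), "relations")
  key <- function(r) paste(r$id, r$ctcf_id, r$relation)
  expect_true(all(key(reduced) %in% key(full)))
})

test_that("category_distribution handles empty and all-outside input", {
  empty <- classify_topology(random_loops(0), random_loops(0))
  expect_equal(nrow(category_distribution(empty)), 0)
  h <- mk_loop("h", 0, 100, 20000, 20100)
  cd <- category_distribution(classify_topology(h, random_loops(0)))
  expect_equal(cd$category, "outside")
  expect_equal(cd$percent, 100)
})

test_that("solo_anchor_report emits the CTCF-free anchor of contain-II", {
  c1 <- ctcf_example()
  x <- rbind(mk_loop("ii", 2900, 3100, 9000, 9100),   # left shared
             mk_loop("iii", 2900, 3100, 6900, 7100))  # both shared
  topo <- classify_topology(x, c1)
  rep <- solo_anchor_report(topo, x)
  expect_equal(rep$id, "ii")
  expect_equal(rep$side, "R")
  expect_equal(rep$start, 9000)
  # planted contain-II solo anchors at promoters annotate as P
  prom <- mk_intervals(8800, 9300)
  none <- mk_intervals(numeric(0), numeric(0))
  lab <- label_anchors(loop_anchors(x), none, none, prom)
  rep2 <- solo_anchor_report(topo, x, lab)
  expect_equal(rep2$composite, "P")
})
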