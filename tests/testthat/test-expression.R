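mk_design <- function(reps = 3,
                      conds = c("untreated", "IAA", "wt_IAA", "mut_IAA")) {
  data.frame(sample = paste0(rep(conds, each = reps), "_rep", seq_len(reps)),
             condition = rep(conds, each = reps))
}

test_that("call_degs: null design yields no calls; errors are informative", {
  set.seed(71)
  des <- mk_design()
  mu <- rlnorm(150, 5, 1)
  counts <- sapply(des$sample, function(s) rnbinom(150, mu = mu, size = 20))
  rownames(counts) <- paste0("g", 1:150)
  res <- call_degs(counts, des, "untreated", "IAA")
  expect_lte(sum(res$status != "unchanged"), 2)
  bad <- des[des$sample != "IAA_rep1" | des$condition != "IAA", ]
  one_rep <- des[c(1:3, 4), ]
  expect_error(call_degs(counts[, one_rep$sample], one_rep, "untreated",
                         "IAA"), "degenerate design")
})

test_that("pooled test equals the closed-form tail sum on one gene", {
  des <- mk_design(2, c("untreated", "IAA"))
  counts <- rbind(gA = c(60, 40, 12, 13))
  colnames(counts) <- des$sample
  res <- call_degs(counts, des, "untreated", "IAA", test = "pooled")
  share <- 25 / 125
  expect_equal(res$pvalue, oracle_binom_p2(25, 125, share))
})

test_that("DEG recall on the simulated design meets the stated power", {
  cfg <- sim_config(seed = 2)
  expr <- simulate_expression(cfg)
  res <- call_degs(expr$counts, expr$design, "untreated", "IAA")
  tg <- expr$truth
  down <- tg$gene_id[tg$direction == "down"]
  recall <- mean(res$status[match(down, res$gene)] == "down")
  expect_gte(recall, 0.7)
})

test_that("intersect_deg_sets: example, invariances, errors", {
  r <- intersect_deg_sets(list(A = c(1, 2, 3), B = c(2, 3, 4), C = c(3, 5)))
  expect_equal(r$consistent, "3")
  expect_equal(rownames(r$membership), as.character(1:5))
  e <- intersect_deg_sets(list(A = 1:3, B = integer(0)))
  expect_equal(length(e$consistent), 0)
  # order- and duplication-invariance
  r2 <- intersect_deg_sets(list(A = c(3, 2, 1, 2), B = c(4, 3, 2), C = c(5, 3)))
  expect_equal(r2$consistent, r$consistent)
  expect_error(intersect_deg_sets(list(1:2)), "at least 2")
  expect_error(intersect_deg_sets(list(A = 1, A = 2)), "unique")
})

test_that("flag_promoter_ctcf flags by window overlap", {
  g <- data.frame(gene_id = c("g1", "g2"), chrom = "chr1",
                  tss = c(5000, 50000), strand = c("+", "+"))
  w <- promoter_windows(g)
  peaks <- mk_intervals(4200, 4600)
  f <- flag_promoter_ctcf(w, peaks)
  expect_equal(as.logical(f), c(TRUE, FALSE))
  expect_equal(attr(f, "fraction"), 0.5)
  f0 <- flag_promoter_ctcf(w, peaks[0, ])
  expect_equal(attr(f0, "fraction"), 0)
})

test_that("classify_rescue implements the three rules and is depth-invariant", {
  des <- mk_design()
  base <- 400
  # stable background genes anchor the CPM scale
  mk_counts <- function(iaa, wt, mut) {
    g <- c(rep(base, 3), rep(iaa, 3), rep(wt, 3), rep(mut, 3))
    m <- rbind(g, bg1 = 5000, bg2 = 8000, bg3 = 12000)
    rownames(m)[1] <- "g"
    colnames(m) <- des$sample
    m
  }
  both <- mk_counts(100, 400, 400)
  expect_equal(classify_rescue(both, des, "g")$rescue_class,
               "loop_independent")
  wt_only <- mk_counts(100, 400, 100)
  expect_equal(classify_rescue(wt_only, des, "g")$rescue_class,
               "loop_dependent")
  neither <- mk_counts(100, 100, 100)
  expect_equal(classify_rescue(neither, des, "g")$rescue_class,
               "not_rescued")
  # uniform depth scaling of one condition must not change the class
  scaled <- both
  scaled[, des$condition == "mut_IAA"] <- scaled[, des$condition == "mut_IAA"] * 7
  expect_equal(classify_rescue(scaled, des, "g")$rescue_class,
               classify_rescue(both, des, "g")$rescue_class)
  expect_error(classify_rescue(both, des[1:9, ], "g"), "missing condition")
})

test_that("iaa_responsive_genes finds genes deregulated in all IAA arms", {
  des <- mk_design()
  m <- rbind(resp = c(rep(400, 3), rep(90, 9)),
             normal = rep(400, 12),
             rescued = c(rep(400, 3), rep(90, 3), rep(400, 6)))
  colnames(m) <- des$sample
  expect_equal(iaa_responsive_genes(m, des), "resp")
})

test_that("partition_deg_by_mechanism is a true partition with the set logic", {
  flags <- c(g1 = TRUE, g2 = TRUE, g3 = FALSE, g4 = FALSE)
  mech <- partition_deg_by_mechanism(c("g1", "g2", "g3", "g4"), flags,
                                     c("g2", "g3"))
  expect_equal(mech$mechanism,
               c("loop_independent_candidate", "cooperative", "loop_only",
                 "neither"))
  expect_equal(sort(mech$gene), sort(c("g1", "g2", "g3", "g4")))
  empty <- partition_deg_by_mechanism(character(0), flags, character(0))
  expect_equal(nrow(empty), 0)
})

test_that("percent_report: printed-precision arithmetic and errors", {
  expect_equal(percent_report(106, 128, 1)$value, 82.8)
  expect_equal(percent_report(106, 128, 1)$label, "82.8% (106/128)")
  expect_equal(percent_report(0, 57, 1)$value, 0)
  expect_equal(percent_report(194, 11777, 2)$value,
               oracle_percent(194, 11777, 2))
  set.seed(72)
  for (i in 1:30) {
    den <- sample(1:5e4, 1); num <- sample(0:den, 1); d <- sample(0:3, 1)
    expect_equal(percent_report(num, den, d)$value,
                 oracle_percent(num, den, d))
  }
  expect_error(percent_report(1, 0), "denominator")
})
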