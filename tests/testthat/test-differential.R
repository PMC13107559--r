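test_that("fold_changes: null, limit, antisymmetry, spreadsheet oracle", {
  x <- data.frame(id = c("a", "b"), count_untreated = c(50, 50),
                  count_IAA = c(50, 50))
  fc <- fold_changes(x, "untreated", "IAA")
  expect_equal(fc$log2fc, c(0, 0))
  # post = 2x pre at equal depth: log2fc -> 1 as counts grow
  big <- data.frame(id = "g", count_untreated = 1e5, count_IAA = 2e5)
  fcb <- fold_changes(big, "untreated", "IAA",
                      totals = c(untreated = 1e6, IAA = 1e6))
  expect_equal(fcb$log2fc, 1, tolerance = 1e-4)
  # antisymmetry with pseudocount 0
  set.seed(51)
  r <- data.frame(id = paste0("r", 1:50),
                  count_untreated = rpois(50, 40) + 1,
                  count_IAA = rpois(50, 40) + 1)
  fwd <- fold_changes(r, "untreated", "IAA", pseudocount = 0)
  rev <- fold_changes(r, "IAA", "untreated", pseudocount = 0)
  expect_equal(fwd$log2fc, -rev$log2fc)
  # independent recomputation
  tot <- c(sum(r$count_untreated), sum(r$count_IAA))
  expect_equal(fwd$log2fc,
               log2((r$count_IAA * 1e6 / tot[2]) /
                      (r$count_untreated * 1e6 / tot[1])))
  expect_error(fold_changes(r, "untreated", "nope"), "unknown condition")
})

test_that("exact binomial p matches binom.test and the closed form", {
  # single loop, counts (100, 25), equal depths
  p_pkg <- looptopo:::.binom_p2(25, 125, 0.5)
  expect_equal(p_pkg, binom.test(25, 125, 0.5)$p.value)
  expect_equal(p_pkg, oracle_binom_p2(25, 125, 0.5))
  set.seed(52)
  for (i in 1:25) {
    n <- sample(1:200, 1); x <- sample(0:n, 1); p <- runif(1, 0.05, 0.95)
    expect_equal(looptopo:::.binom_p2(x, n, p),
                 binom.test(x, n, p)$p.value, tolerance = 1e-12)
  }
})

test_that("call_differential: null gives zero calls; caller has power", {
  set.seed(53)
  lam <- rlnorm(300, 4, 0.8)
  x <- data.frame(id = paste0("l", 1:300), count_untreated = rpois(300, lam),
                  count_IAA = NA)
  x$count_IAA <- x$count_untreated  # identical libraries duplicated
  res <- call_differential(x, "untreated", "IAA")
  expect_equal(sum(res$call != "unchanged"), 0)
  # planted 4-fold drops on 5% of loops via the simulator
  cfg <- sim_config(seed = 9, n_h3k27ac = 800,
                    class_mix = c(contain_III = 0.05, outside = 0.95))
  arch <- simulate_ctcf_architecture(cfg)
  pl <- plant_h3k27ac_interactions(cfg, arch)
  d <- call_differential(pl$interactions, "untreated", "IAA")
  planted <- pl$truth$id[pl$truth$effect < 1]
  called <- d$id[d$call == "down"]
  recall <- mean(planted %in% called)
  fdr <- if (length(called)) mean(!(called %in% planted)) else 0
  expect_gte(recall, 0.8)
  expect_lte(fdr, 0.1)
})

test_that("mann_whitney_u: pinned example, identical groups, ties", {
  r <- mann_whitney_u(c(1, 2, 3), c(4, 5, 6))
  expect_equal(r$U, 0)
  expect_equal(r$pvalue, 0.1)  # 2 of 20 arrangements as extreme
  expect_equal(mann_whitney_u(c(2, 2, 2), c(2, 2, 2))$pvalue, 1)
  expect_equal(mann_whitney_u(1:5, 1:5)$pvalue, 1)
  expect_error(mann_whitney_u(numeric(0), 1:3), "non-empty")
})

test_that("mann_whitney_u exact path equals enumeration (spot checks)", {
  set.seed(54)
  for (i in 1:20) {
    n <- sample(2:6, 1); m <- sample(2:6, 1)
    a <- runif(n); b <- runif(m)
    expect_equal(mann_whitney_u(a, b)$pvalue, oracle_mwu_enum(a, b),
                 tolerance = 1e-12)
  }
})

test_that("mann_whitney_u approximation agrees with wilcox.test", {
  set.seed(55)
  a <- rnorm(40); b <- rnorm(35, 0.4)
  got <- mann_whitney_u(a, b)
  ref <- wilcox.test(a, b, correct = TRUE, exact = FALSE)
  expect_equal(got$pvalue, ref$p.value, tolerance = 1e-10)
})

test_that("BH-FDR matches the step-by-step oracle and is order-invariant", {
  set.seed(56)
  p <- runif(200)^2
  expect_equal(p.adjust(p, "BH"), oracle_bh(p))
  o <- sample(200)
  expect_equal(p.adjust(p, "BH")[o], p.adjust(p[o], "BH"))
})

test_that("strength strata: degenerate input collapses to one stratum", {
  st <- strength_strata(rep(3, 10))
  expect_equal(length(unique(st$stratum)), 1)
})

test_that("stratification report and balance antisymmetry", {
  set.seed(57)
  labels <- data.frame(id = paste0("i", 1:40),
                       category = "contain_and_cross",
                       max_contain_strength = runif(40, 1, 10),
                       max_cross_strength = runif(40, 1, 10))
  results <- data.frame(id = labels$id, log2fc = rnorm(40))
  g <- contain_cross_grid(labels, results)
  swapped <- labels
  swapped$max_contain_strength <- labels$max_cross_strength
  swapped$max_cross_strength <- labels$max_contain_strength
  g2 <- contain_cross_grid(swapped, results)
  expect_equal(g$assignments$balance, -g2$assignments$balance)
  # empty stratum reported, not an error
  empty <- stratify_by_ctcf_strength(
    data.frame(id = character(), category = character(),
               max_cross_strength = numeric()),
    results, "cross")
  expect_equal(nrow(empty$table), 0)
})

test_that("class_response_report errors on missing join keys", {
  labels <- data.frame(id = c("a", "b"), category = c("contain", "outside"),
                       contain_subtype = c(3L, NA))
  results <- data.frame(id = "a", log2fc = -1)
  expect_error(class_response_report(labels, results), "b")
})
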