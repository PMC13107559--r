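test_that("ctcf_centered_windows: arithmetic, summit, clipping, errors", {
  s <- mk_intervals(9000, 11000)  # midpoint 10,000
  w <- ctcf_centered_windows(s, 300)
  expect_equal(c(w$start, w$end), c(9850, 10150))
  w2 <- ctcf_centered_windows(s, 2)
  expect_equal(w2$end - w2$start, 2)
  s2 <- mk_intervals(0, 100)
  w3 <- ctcf_centered_windows(s2, 300, chrom_sizes = c(chr1 = 1e6))
  expect_equal(w3$start, 0)
  ssum <- mk_intervals(9000, 11000); ssum$summit <- 100  # center 9,100
  wsum <- ctcf_centered_windows(ssum, 300)
  expect_equal(c(wsum$start, wsum$end), c(8950, 9250))
  expect_error(ctcf_centered_windows(s, -10), "width")
  expect_error(ctcf_centered_windows(s, 301), "even")
})

test_that("partition_by_ctcf_overlap is a partition; empty peak set", {
  set.seed(61)
  down <- mk_intervals(p <- sort(sample(seq(0, 1e6, 500), 60)), p + 300,
                       name = paste0("s", 1:60))
  peaks <- mk_intervals(q <- sort(sample(seq(0, 1e6, 700), 40)), q + 400)
  pp <- partition_by_ctcf_overlap(down, peaks)
  expect_equal(nrow(pp$group1) + nrow(pp$group2), nrow(down))
  expect_equal(length(intersect(pp$group1$name, pp$group2$name)), 0)
  brute <- sapply(seq_len(nrow(down)), function(i)
    any(peaks$start < down$end[i] & down$start[i] < peaks$end))
  expect_equal(pp$overlap_fraction, mean(brute))
  none <- partition_by_ctcf_overlap(down, peaks[0, ])
  expect_equal(nrow(none$group1), 0)
  expect_equal(none$overlap_fraction, 0)
})

test_that("promoter_fraction_of_down_sites counts sites once, genes all", {
  prom <- mk_intervals(c(1000, 2600), c(2500, 4000), name = c("g1", "g2"))
  site_two <- mk_intervals(2400, 2700)  # spans both promoters
  r <- promoter_fraction_of_down_sites(site_two, prom)
  expect_equal(r$n_promoter_sites, 1)
  expect_equal(r$genes_hit, c("g1", "g2"))
  far <- mk_intervals(9e5, 9.01e5)
  r0 <- promoter_fraction_of_down_sites(far, prom)
  expect_equal(r0$n_promoter_sites, 0)
  expect_equal(r0$n_genes, 0)
  set.seed(62)
  sites <- mk_intervals(p <- sort(sample(seq(0, 1e5, 50), 100)), p + 200)
  brute_sites <- sapply(seq_len(nrow(sites)), function(i)
    any(prom$start < sites$end[i] & sites$start[i] < prom$end))
  rr <- promoter_fraction_of_down_sites(sites, prom)
  expect_equal(rr$n_promoter_sites, sum(brute_sites))
})

test_that("motif_tss_distance: signed, strand-flipped, centered", {
  genes <- data.frame(gene_id = c("gp", "gm", "g0"),
                      chrom = c("chr1", "chr2", "chr1"),
                      tss = c(1000, 1000, 5000), strand = c("+", "-", "+"))
  motifs <- mk_intervals(c(934, 1048, 4991), c(953, 1067, 5010),
                         chrom = c("chr1", "chr2", "chr1"))
  # centers 943 (chr1), 1057 (chr2), 5000 (chr1)
  r <- motif_tss_distance(motifs, genes)
  expect_equal(unname(r$distances["gp"]), -57)
  expect_equal(unname(r$distances["gm"]), -57)
  expect_equal(unname(r$distances["g0"]), 0)
  expect_equal(r$n_excluded, 0)
  # gene with no promoter motif is excluded and counted
  g2 <- rbind(genes, data.frame(gene_id = "gx", chrom = "chr1",
                                tss = 900000, strand = "+"))
  r2 <- motif_tss_distance(motifs, g2)
  expect_equal(r2$n_excluded, 1)
})

test_that("planted -57 bp offset is recovered within the stated band", {
  for (seed in c(3, 8)) {
    cfg <- sim_config(seed = seed)
    st <- simulate_study(cfg)
    tg <- st$truth$genes
    r <- motif_tss_distance(st$ctcf$motifs, st$gene_models,
                            gene_subset = tg$gene_id[tg$direction == "down"])
    expect_true(r$median >= -65 && r$median <= -49)
  }
})

test_that("null accessibility simulation stays within binomial bounds", {
  cfg <- sim_config(seed = 17, atac_effect_fraction = 0, atac_n_background = 400)
  arch <- simulate_ctcf_architecture(cfg)
  atac <- simulate_atac(cfg, arch$peaks)
  expect_equal(sum(atac$truth$affected), 0)
  res <- call_differential_accessibility(atac$windows, "untreated", "IAA")
  # BH under a complete null: any call at all is rare
  expect_lte(sum(res$call != "unchanged"), ceiling(0.05 * nrow(res)))
})

test_that("effect size 1.0 is a null (distributionally identical)", {
  cfg <- sim_config(seed = 18, atac_effect_size = 1)
  arch <- simulate_ctcf_architecture(cfg)
  atac <- simulate_atac(cfg, arch$peaks)
  aff <- atac$truth$affected
  w <- atac$windows
  p <- mann_whitney_u(w$count_IAA[aff] / pmax(w$count_untreated[aff], 1),
                      w$count_IAA[!aff] / pmax(w$count_untreated[!aff], 1))$pvalue
  expect_gt(p, 0.001)
})
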