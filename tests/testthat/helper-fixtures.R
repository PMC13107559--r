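# Small in-code fixtures shared across test files.

mk_loop <- function(id, s1, e1, s2, e2, chrom = "chr1", strength = 1,
                    pre = 10, post = 10) {
  loops(id = id, chrom = chrom, start1 = s1, end1 = e1, start2 = s2,
        end2 = e2, strength = strength,
        counts = list(untreated = pre, IAA = post))
}

# random canonical loops: anchors of width `aw` with a guaranteed gap
random_loops <- function(n, genome = 1e7, aw = 500, min_gap = 5e3,
                         max_span = 3e5, prefix = "L") {
  s1 <- round(runif(n, 0, genome - max_span - 2 * aw - min_gap))
  gap <- round(runif(n, min_gap, max_span))
  loops(id = paste0(prefix, seq_len(n)), chrom = "chr1",
        start1 = s1, end1 = s1 + aw,
        start2 = s1 + aw + gap, end2 = s1 + 2 * aw + gap,
        strength = rlnorm(n, 2, 0.5),
        counts = list(untreated = rpois(n, 20), IAA = rpois(n, 20)))
}

mk_intervals <- function(starts, ends, chrom = "chr1", ...) {
  intervals(chrom = chrom, start = starts, end = ends, ...)
}
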