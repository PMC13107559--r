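# Independent oracles: deliberately naive re-derivations (per-bp bitmaps,
# scalar double loops, full enumerations) kept free of the package's
# vectorized/indexed code paths.

# per-base boolean array union coverage
oracle_union_coverage <- function(spans, chrom_sizes) {
  covered <- 0
  for (ch in names(chrom_sizes)) {
    bitmap <- logical(chrom_sizes[[ch]])
    si <- spans[spans$chrom == ch, , drop = FALSE]
    if (nrow(si)) for (i in seq_len(nrow(si))) {
      lo <- max(0, si$start[i]); hi <- min(chrom_sizes[[ch]], si$end[i])
      if (hi > lo) bitmap[(lo + 1):hi] <- TRUE
    }
    covered <- covered + sum(bitmap)
  }
  covered / sum(chrom_sizes)
}

# scalar re-derivation of the pairwise relation rules
oracle_relate <- function(h, c, slack = 0, span_mode = "midpoint") {
  if (h$chrom != c$chrom) return("none")
  mid <- function(s, e) floor((s + e) / 2)
  if (span_mode == "midpoint") {
    S0 <- mid(c$start1, c$end1); S1 <- mid(c$start2, c$end2)
  } else {
    S0 <- c$start1; S1 <- c$end2
  }
  # >=1 bp intersection of a expanded by slack with b
  ov <- function(as, ae, bs, be) max(as - slack, bs) < min(ae + slack, be)
  hm1 <- mid(h$start1, h$end1); hm2 <- mid(h$start2, h$end2)
  sLL <- ov(h$start1, h$end1, c$start1, c$end1)
  sRR <- ov(h$start2, h$end2, c$start2, c$end2)
  sLR <- ov(h$start1, h$end1, c$start2, c$end2)
  sRL <- ov(h$start2, h$end2, c$start1, c$end1)
  if ((hm1 <= S0 || sLL) && (hm2 >= S1 || sRR))
    return(paste0("contain_", sLL + sRR))
  strict_in <- function(x) x > S0 && x < S1
  strict_out <- function(x) x < S0 || x > S1
  if ((strict_in(hm1) && strict_out(hm2)) ||
      (strict_in(hm2) && strict_out(hm1))) return("cross")
  a1s <- sLL || sLR; a2s <- sRL || sRR
  if (strict_in(hm1) && strict_in(hm2) && !a1s && !a2s) return("inside")
  if (sum(a1s, a2s) == 1 &&
      ((a1s && strict_out(hm2)) || (a2s && strict_out(hm1))))
    return("neighbor")
  "none"
}

# full double-loop classification using the scalar oracle plus the
# category combination rule re-stated
oracle_classify <- function(h3k, ctcf, slack = 0, span_mode = "midpoint") {
  out <- character(nrow(h3k))
  subtype <- rep(NA_integer_, nrow(h3k))
  for (i in seq_len(nrow(h3k))) {
    rels <- character(0); subs <- integer(0)
    for (j in seq_len(nrow(ctcf))) {
      r <- oracle_relate(h3k[i, ], ctcf[j, ], slack, span_mode)
      if (r == "none") next
      if (startsWith(r, "contain_")) {
        subs <- c(subs, as.integer(sub("contain_", "", r)) + 1L)
        r <- "contain"
      }
      rels <- c(rels, r)
    }
    u <- unique(rels)
    out[i] <- if (!length(u)) "outside"
    else if (length(u) == 1) u
    else if (length(u) == 2 && all(c("contain", "cross") %in% u))
      "contain_and_cross"
    else "other_composite"
    if (length(subs)) subtype[i] <- max(subs)
  }
  data.frame(id = h3k$id, category = out, contain_subtype = subtype,
             stringsAsFactors = FALSE)
}

# two-sided Mann-Whitney p by complete enumeration of all C(n+m, n)
# assignments of the pooled midranks
oracle_mwu_enum <- function(a, b) {
  n <- length(a); m <- length(b)
  r <- rank(c(a, b))
  U_obs <- sum(r[seq_len(n)]) - n * (n + 1) / 2
  combos <- utils::combn(n + m, n)
  U_all <- apply(combos, 2, function(idx) sum(r[idx]) - n * (n + 1) / 2)
  lo <- mean(U_all <= U_obs + 1e-9)
  hi <- mean(U_all >= U_obs - 1e-9)
  min(1, 2 * min(lo, hi))
}

# step-by-step Benjamini-Hochberg
oracle_bh <- function(p) {
  n <- length(p)
  o <- order(p)
  adj <- numeric(n)
  running <- 1
  for (k in n:1) {
    running <- min(running, p[o[k]] * n / k)
    adj[o[k]] <- running
  }
  adj
}

# exact two-sided binomial p by direct tail summation
oracle_binom_p2 <- function(x, n, p) {
  d <- dbinom(0:n, n, p)
  sum(d[d <= d[x + 1] * (1 + 1e-7)])
}

# round-half-up percentage via integer arithmetic (long-division style)
oracle_percent <- function(num, den, decimals) {
  scaled <- num * 100 * 10^decimals
  q <- scaled %/% den
  r <- scaled %% den
  if (2 * r >= den) q <- q + 1
  q / 10^decimals
}
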