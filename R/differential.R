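# Differential interaction / accessibility machinery for one library per
# condition: CPM normalization, an exact two-sided binomial test of the
# post-condition count against its depth share, BH-FDR, and the
# Mann-Whitney U comparisons used in all class- and strength-stratified
# reports.

#' CPM normalization and per-feature log2 fold change
#'
#' `norm = count * 1e6 / library_total`; `log2fc = log2((norm_post + pc) /
#' (norm_pre + pc))`. With `pseudocount = 0` the fold change is exactly
#' antisymmetric under swapping the condition labels.
#'
#' @param x feature table with `id` and `count_<condition>` columns (loops,
#'   ATAC windows, ...).
#' @param pre,post condition names.
#' @param pseudocount added on the CPM scale (default 1).
#' @param totals optional named library totals; default column sums.
#' @return data.frame `id`, `count_pre`, `count_post`, `norm_pre`,
#'   `norm_post`, `log2fc`.
#' @export
fold_changes <- function(x, pre, post, pseudocount = 1, totals = NULL) {
  for (cond in c(pre, post))
    if (!paste0("count_", cond) %in% names(x))
      stop("unknown condition: ", cond)
  cpre <- x[[paste0("count_", pre)]]
  cpost <- x[[paste0("count_", post)]]
  if (is.null(totals)) totals <- c(sum(cpre), sum(cpost))
  else totals <- c(totals[[pre]], totals[[post]])
  if (any(totals <= 0)) stop("zero library total")
  norm_pre <- cpre * 1e6 / totals[1]
  norm_post <- cpost * 1e6 / totals[2]
  data.frame(id = x$id, count_pre = cpre, count_post = cpost,
             norm_pre = norm_pre, norm_post = norm_post,
             log2fc = log2((norm_post + pseudocount) /
                             (norm_pre + pseudocount)),
             stringsAsFactors = FALSE)
}

# Exact two-sided binomial p-value: sum of all outcome probabilities not
# exceeding the observed one (the usual minlike definition).
.binom_p2 <- function(x, n, p) {
  if (n == 0) return(1)
  d <- stats::dbinom(0:n, n, p)
  min(1, sum(d[d <= d[x + 1] * (1 + 1e-7)]))
}

#' Call differential features between two conditions
#'
#' Designed for single pooled libraries per condition (HiChIP interactions,
#' ATAC windows). Under the no-change null the post count, conditional on
#' the feature total, is binomial with the post library's depth share as
#' success probability; the test is the exact two-sided binomial test, with
#' BH-FDR across all features. A feature is called `up`/`down` only when
#' both `fdr <= alpha` and `|log2fc| >= min_lfc`.
#'
#' @inheritParams fold_changes
#' @param alpha FDR threshold (default 0.05).
#' @param min_lfc minimum |log2 fold change| (default 1, i.e. 2-fold).
#' @return data.frame adding `pvalue`, `fdr`, `call` to [fold_changes()].
#' @export
call_differential <- function(x, pre, post, alpha = 0.05, min_lfc = 1,
                              pseudocount = 1, totals = NULL) {
  fc <- fold_changes(x, pre, post, pseudocount = pseudocount, totals = totals)
  tot_pre <- if (is.null(totals)) sum(fc$count_pre) else totals[[pre]]
  tot_post <- if (is.null(totals)) sum(fc$count_post) else totals[[post]]
  share <- tot_post / (tot_pre + tot_post)
  n <- fc$count_pre + fc$count_post
  fc$pvalue <- vapply(seq_len(nrow(fc)), function(i)
    .binom_p2(fc$count_post[i], n[i], share), numeric(1))
  fc$fdr <- stats::p.adjust(fc$pvalue, method = "BH")
  fc$call <- "unchanged"
  sig <- fc$fdr <= alpha & abs(fc$log2fc) >= min_lfc
  fc$call[sig & fc$log2fc > 0] <- "up"
  fc$call[sig & fc$log2fc < 0] <- "down"
  fc
}

#' Two-sided Mann-Whitney U test
#'
#' U is the number of (a, b) pairs with `a > b` (ties count 1/2). For
#' tie-free samples with `min(n, m) <= 8` the exact null distribution of U
#' is used; otherwise the normal approximation with tie and continuity
#' corrections. Two identical groups give p = 1.
#'
#' @param a,b non-empty numeric vectors.
#' @return list with `U` (for group `a`) and `pvalue`.
#' @export
mann_whitney_u <- function(a, b) {
  a <- as.numeric(a); b <- as.numeric(b)
  if (!length(a) || !length(b)) stop("both groups must be non-empty")
  n <- length(a); m <- length(b)
  pooled <- c(a, b)
  r <- rank(pooled)
  U <- sum(r[seq_len(n)]) - n * (n + 1) / 2
  ties <- table(pooled)
  has_ties <- any(ties > 1)
  if (!has_ties && min(n, m) <= 8) {
    lo <- stats::pwilcox(U, n, m)
    hi <- 1 - stats::pwilcox(U - 1, n, m)
    p <- min(1, 2 * min(lo, hi))
  } else {
    N <- n + m
    mu <- n * m / 2
    tie_term <- sum(ties^3 - ties) / (N * (N - 1))
    sigma2 <- n * m / 12 * ((N + 1) - tie_term)
    if (sigma2 <= 0) return(list(U = U, pvalue = 1))
    z <- (abs(U - mu) - 0.5) / sqrt(sigma2)
    p <- min(1, 2 * stats::pnorm(-max(z, 0)))
  }
  list(U = U, pvalue = p)
}

#' Quantile strata of CTCF loop strength
#'
#' @param strengths numeric vector.
#' @param n_bins number of quantile bins (default 2, a median split).
#' @return list with integer `stratum` per value, `labels` (weak/strong for
#'   2 bins, else `q1..qk`), and the `boundaries` used. Degenerate inputs
#'   (all equal) collapse to a single stratum.
#' @export
strength_strata <- function(strengths, n_bins = 2) {
  qs <- stats::quantile(strengths, probs = seq(0, 1, length.out = n_bins + 1),
                        na.rm = TRUE, names = FALSE)
  qs <- unique(qs)
  k <- length(qs) - 1
  if (k < 1) {
    stratum <- rep(1L, length(strengths))
    k <- 1
  } else {
    stratum <- as.integer(cut(strengths, breaks = qs, include.lowest = TRUE))
  }
  labels <- if (k == 2) c("weak", "strong") else paste0("q", seq_len(k))
  list(stratum = stratum, labels = labels, boundaries = qs)
}

#' Fold-change distributions stratified by overlapped CTCF loop strength
#'
#' For interactions of the given category, strengths of the relevant CTCF
#' relation (`max_cross_strength` for cross, `max_contain_strength` for
#' contain) are binned by quantiles; the report gives per-stratum n, median
#' and IQR of log2 fold change, plus a two-sided Mann-Whitney p for every
#' stratum pair. Empty strata are reported as empty, not errors.
#'
#' @param labels [classify_topology()] output.
#' @param results [call_differential()] output, joined on `id`.
#' @param category `"cross"` or `"contain"`.
#' @param n_bins quantile bins (default 2: weak/strong).
#' @return list with `table` (per-stratum summary), `pairwise` (MWU p
#'   matrix) and `assignments`.
#' @export
stratify_by_ctcf_strength <- function(labels, results, category = "cross",
                                      n_bins = 2) {
  stopifnot(category %in% c("cross", "contain"))
  sel <- labels[labels$category == category, , drop = FALSE]
  strength_col <- paste0("max_", category, "_strength")
  m <- match(sel$id, results$id)
  if (any(is.na(m)))
    stop("missing differential results for: ",
         paste(utils::head(sel$id[is.na(m)], 5), collapse = ", "))
  lfc <- results$log2fc[m]
  if (!nrow(sel))
    return(list(table = data.frame(), pairwise = matrix(numeric(0), 0, 0),
                assignments = data.frame()))
  st <- strength_strata(sel[[strength_col]], n_bins = n_bins)
  k <- length(st$labels)
  tab <- do.call(rbind, lapply(seq_len(k), function(i) {
    v <- lfc[st$stratum == i]
    data.frame(stratum = st$labels[i], n = length(v),
               median_log2fc = if (length(v)) stats::median(v) else NA_real_,
               iqr = if (length(v)) stats::IQR(v) else NA_real_,
               stringsAsFactors = FALSE)
  }))
  pw <- matrix(NA_real_, k, k, dimnames = list(st$labels, st$labels))
  for (i in seq_len(k)) for (j in seq_len(k)) {
    vi <- lfc[st$stratum == i]; vj <- lfc[st$stratum == j]
    if (i != j && length(vi) && length(vj))
      pw[i, j] <- mann_whitney_u(vi, vj)$pvalue
  }
  list(table = tab, pairwise = pw, boundaries = st$boundaries,
       assignments = data.frame(id = sel$id, stratum = st$labels[st$stratum],
                                strength = sel[[strength_col]], log2fc = lfc,
                                stringsAsFactors = FALSE))
}

#' Contain-and-cross strength grid with balance statistic
#'
#' For contain & cross interactions, a 2-D grid over (contain strength bin x
#' cross strength bin) with the per-interaction balance statistic
#' `log2(max_contain_strength / max_cross_strength)`; positive balance means
#' the promotional (contain) loop dominates the insulating (cross) loop.
#'
#' @inheritParams stratify_by_ctcf_strength
#' @return list with per-interaction `assignments` and a per-cell summary
#'   `grid` (n, median log2fc, median balance).
#' @export
contain_cross_grid <- function(labels, results, n_bins = 2) {
  sel <- labels[labels$category == "contain_and_cross", , drop = FALSE]
  m <- match(sel$id, results$id)
  if (any(is.na(m)))
    stop("missing differential results for: ",
         paste(utils::head(sel$id[is.na(m)], 5), collapse = ", "))
  if (!nrow(sel))
    return(list(assignments = data.frame(), grid = data.frame()))
  stc <- strength_strata(sel$max_contain_strength, n_bins = n_bins)
  stx <- strength_strata(sel$max_cross_strength, n_bins = n_bins)
  asg <- data.frame(id = sel$id,
                    contain_stratum = stc$labels[stc$stratum],
                    cross_stratum = stx$labels[stx$stratum],
                    balance = log2(sel$max_contain_strength /
                                     sel$max_cross_strength),
                    log2fc = results$log2fc[m], stringsAsFactors = FALSE)
  grid <- do.call(rbind, lapply(stc$labels, function(ci)
    do.call(rbind, lapply(stx$labels, function(xi) {
      v <- asg[asg$contain_stratum == ci & asg$cross_stratum == xi, ]
      data.frame(contain_stratum = ci, cross_stratum = xi, n = nrow(v),
                 median_log2fc = if (nrow(v)) stats::median(v$log2fc) else NA_real_,
                 median_balance = if (nrow(v)) stats::median(v$balance) else NA_real_,
                 stringsAsFactors = FALSE)
    }))))
  list(assignments = asg, grid = grid)
}

#' Per-category fold-change response table
#'
#' Summarizes log2 fold changes per topology category, splitting contain by
#' subtype (I/II/III), with a two-sided Mann-Whitney p against the outside
#' category as reference.
#'
#' @param labels [classify_topology()] output.
#' @param results [call_differential()] output.
#' @return data.frame `group`, `n`, `median_log2fc`, `iqr`,
#'   `p_vs_outside`.
#' @export
class_response_report <- function(labels, results) {
  m <- match(labels$id, results$id)
  if (any(is.na(m)))
    stop("missing differential results for: ",
         paste(utils::head(labels$id[is.na(m)], 5), collapse = ", "))
  lfc <- results$log2fc[m]
  groups <- list()
  for (sub in 1:3)
    groups[[paste0("contain_", c("I", "II", "III")[sub])]] <-
      lfc[labels$category == "contain" & !is.na(labels$contain_subtype) &
            labels$contain_subtype == sub]
  for (cat in c("contain_and_cross", "cross", "neighbor", "inside",
                "other_composite", "outside"))
    groups[[cat]] <- lfc[labels$category == cat]
  ref <- groups[["outside"]]
  do.call(rbind, lapply(names(groups), function(g) {
    v <- groups[[g]]
    p <- if (g != "outside" && length(v) && length(ref))
      mann_whitney_u(v, ref)$pvalue else NA_real_
    data.frame(group = g, n = length(v),
               median_log2fc = if (length(v)) stats::median(v) else NA_real_,
               iqr = if (length(v)) stats::IQR(v) else NA_real_,
               p_vs_outside = p, stringsAsFactors = FALSE)
  }))
}
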