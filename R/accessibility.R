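# ATAC integration around CTCF sites: differential accessibility of window
# counts (sharing the exact-binomial/CPM machinery with the interaction
# caller), CTCF-overlap partition of lost sites, fixed-width CTCF-centered
# windows, promoter annotation of lost sites, and signed motif-to-TSS
# distances.

#' Differential accessibility of window counts
#'
#' Identical machinery to [call_differential()]; provided as a named entry
#' point for ATAC window tables.
#'
#' @inheritParams call_differential
#' @return [call_differential()] result with an `n_up` / `n_down` summary
#'   attached as `attr(, "summary")`.
#' @export
call_differential_accessibility <- function(x, pre, post, alpha = 0.05,
                                            min_lfc = 1, pseudocount = 1,
                                            totals = NULL) {
  res <- call_differential(x, pre, post, alpha = alpha, min_lfc = min_lfc,
                           pseudocount = pseudocount, totals = totals)
  attr(res, "summary") <- c(n_up = sum(res$call == "up"),
                            n_down = sum(res$call == "down"),
                            n_unchanged = sum(res$call == "unchanged"))
  res
}

#' Partition lost accessible sites by CTCF peak overlap
#'
#' Group 1 = sites overlapping a CTCF ChIP peak; Group 2 = the remainder.
#' The two groups partition the input. For Group 2 the fraction containing
#' a CTCF motif is reported, and motif scores hitting Group 1 vs Group 2
#' sites are compared by a two-sided Mann-Whitney test (weak-motif
#' assessment as a distribution comparison, not a threshold call).
#'
#' @param down_sites interval table of lost accessible sites.
#' @param ctcf_peaks interval table of CTCF peaks.
#' @param ctcf_motifs optional stranded, scored motif interval table.
#' @param slack overlap tolerance in bp.
#' @return list with `group1`, `group2`, `overlap_fraction`,
#'   `group2_motif_fraction`, `motif_score_p`.
#' @export
partition_by_ctcf_overlap <- function(down_sites, ctcf_peaks,
                                      ctcf_motifs = NULL, slack = 0) {
  in1 <- overlaps_any(down_sites, ctcf_peaks, slack = slack)
  group1 <- down_sites[in1, , drop = FALSE]
  group2 <- down_sites[!in1, , drop = FALSE]
  out <- list(group1 = group1, group2 = group2,
              overlap_fraction = if (nrow(down_sites))
                nrow(group1) / nrow(down_sites) else NA_real_,
              group2_motif_fraction = NA_real_, motif_score_p = NA_real_)
  if (!is.null(ctcf_motifs) && nrow(ctcf_motifs)) {
    out$group2_motif_fraction <- if (nrow(group2))
      mean(overlaps_any(group2, ctcf_motifs, slack = slack)) else NA_real_
    if (!is.null(ctcf_motifs$score)) {
      s1 <- ctcf_motifs$score[overlaps_any(ctcf_motifs, group1, slack = slack)]
      s2 <- ctcf_motifs$score[overlaps_any(ctcf_motifs, group2, slack = slack)]
      if (length(s1) && length(s2))
        out$motif_score_p <- mann_whitney_u(s1, s2)$pvalue
    }
  }
  out
}

#' Fixed-width windows centered on CTCF sites
#'
#' The window is `[center - width/2, center + width/2)` around each site's
#' summit (when a `summit` offset column is present) or interval midpoint.
#'
#' @param sites interval table, optionally with `summit` (offset from
#'   `start`) and `name` columns.
#' @param width even window width in bp (default 300).
#' @param chrom_sizes optional genome for clipping.
#' @return interval table inheriting site names.
#' @export
ctcf_centered_windows <- function(sites, width = 300, chrom_sizes = NULL) {
  if (width <= 0) stop("width must be > 0")
  if (width %% 2 != 0) stop("width must be even")
  check_intervals(sites)
  center <- if (!is.null(sites$summit)) sites$start + sites$summit
  else interval_midpoints(sites)
  out <- data.frame(chrom = sites$chrom,
                    start = pmax(0, center - width / 2),
                    end = center + width / 2,
                    name = if (!is.null(sites$name)) sites$name
                    else paste0("site_", seq_len(nrow(sites))),
                    stringsAsFactors = FALSE)
  if (!is.null(chrom_sizes)) out <- clip_intervals(out, chrom_sizes, warn = FALSE)
  out
}

#' Lost accessible sites within promoter regions
#'
#' @param down_sites interval table of lost sites.
#' @param prom_windows [promoter_windows()] output (gene ids in `name`).
#' @param slack overlap tolerance in bp.
#' @return list with `n_promoter_sites`, `genes_hit` (distinct gene ids) and
#'   `fraction` of sites in promoters. A site spanning several promoters
#'   counts once but hits every gene.
#' @export
promoter_fraction_of_down_sites <- function(down_sites, prom_windows,
                                            slack = 0) {
  hits <- .overlap_hits(down_sites, prom_windows, slack = slack)
  n_sites <- length(unique(hits$query))
  genes <- sort(unique(prom_windows$name[hits$subject]))
  list(n_promoter_sites = n_sites, genes_hit = genes,
       n_genes = length(genes),
       fraction = if (nrow(down_sites)) n_sites / nrow(down_sites) else NA_real_)
}

#' Signed motif-center-to-TSS distances
#'
#' Each gene is assigned its nearest motif whose center lies within the
#' promoter window; the signed distance `motif_center - TSS` is flipped by
#' gene strand so that negative always means upstream. Genes without a
#' promoter motif are excluded and counted.
#'
#' @param motifs stranded motif interval table.
#' @param genes gene model data.frame (`gene_id`, `chrom`, `tss`, `strand`).
#' @param gene_subset optional gene ids to restrict to.
#' @param upstream,downstream promoter window extents in bp.
#' @param bin histogram bin width in bp for the mode (default 10).
#' @return list with per-gene `distances`, `median`, `mode` (center of the
#'   densest bin) and `n_excluded`.
#' @export
motif_tss_distance <- function(motifs, genes, gene_subset = NULL,
                               upstream = 1000, downstream = 1000, bin = 10) {
  if (!is.null(gene_subset))
    genes <- genes[genes$gene_id %in% gene_subset, , drop = FALSE]
  centers <- interval_midpoints(motifs)
  dist <- rep(NA_real_, nrow(genes))
  for (i in seq_len(nrow(genes))) {
    onchr <- which(motifs$chrom == genes$chrom[i])
    if (!length(onchr)) next
    plus <- genes$strand[i] == "+"
    lo <- genes$tss[i] - if (plus) upstream else downstream
    hi <- genes$tss[i] + if (plus) downstream else upstream
    cand <- onchr[centers[onchr] >= lo & centers[onchr] <= hi]
    if (!length(cand)) next
    raw <- centers[cand] - genes$tss[i]
    best <- cand[which.min(abs(raw))]
    d <- centers[best] - genes$tss[i]
    dist[i] <- if (plus) d else -d
  }
  ok <- !is.na(dist)
  d <- dist[ok]
  mode <- NA_real_
  if (length(d)) {
    breaks <- seq(floor(min(d) / bin) * bin, ceiling(max(d) / bin) * bin + bin,
                  by = bin)
    h <- hist(d, breaks = breaks, plot = FALSE)
    mode <- h$mids[which.max(h$counts)]
  }
  list(distances = stats::setNames(d, genes$gene_id[ok]),
       median = if (length(d)) stats::median(d) else NA_real_,
       mode = mode, n_excluded = sum(!ok))
}
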