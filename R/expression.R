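# Expression integration under the four-condition degron design (untreated,
# IAA, oeCTCF-wt + IAA, oeCTCF-mut + IAA): DEG calling, cross-dataset set
# intersections, promoter CTCF flags, wt/mut rescue classification, and the
# mechanism partition of downregulated genes.

#' Call differentially expressed genes between two conditions
#'
#' The default test is the edgeR quasi-likelihood F-test (robust to the
#' replicate-level overdispersion that RNA-seq counts carry). The
#' `"pooled"` alternative is a transparent exact rate-ratio (binomial) test
#' on replicate-pooled counts; it is exact under Poisson sampling but
#' anticonservative when replicates are overdispersed, and is kept for
#' small worked examples and as the closed-form reference path.
#'
#' @param counts integer matrix, genes x samples, with rownames and
#'   colnames.
#' @param design data.frame with `sample`, `condition`.
#' @param pre,post condition names to contrast (log2fc is post vs pre).
#' @param alpha FDR threshold (default 0.05).
#' @param min_lfc minimum |log2fc| (default 1).
#' @param test `"qlf"` (default) or `"pooled"`.
#' @return data.frame `gene`, `log2fc`, `pvalue`, `fdr`, `status` in
#'   `up`/`down`/`unchanged`.
#' @export
call_degs <- function(counts, design, pre, post, alpha = 0.05, min_lfc = 1,
                      test = c("qlf", "pooled")) {
  test <- match.arg(test)
  if (!all(c("sample", "condition") %in% names(design)))
    stop("design needs 'sample' and 'condition' columns")
  for (cond in c(pre, post)) {
    k <- sum(design$condition == cond)
    if (k < 2) stop("degenerate design: condition '", cond,
                    "' has ", k, " replicate(s), need >= 2")
  }
  sel <- design[design$condition %in% c(pre, post), , drop = FALSE]
  mat <- counts[, sel$sample, drop = FALSE]
  grp <- factor(sel$condition, levels = c(pre, post))
  if (test == "qlf") {
    y <- edgeR::DGEList(counts = mat, group = grp)
    y <- edgeR::calcNormFactors(y)
    mm <- stats::model.matrix(~grp)
    y <- edgeR::estimateDisp(y, mm)
    fit <- edgeR::glmQLFit(y, mm)
    qlf <- edgeR::glmQLFTest(fit, coef = 2)
    tab <- qlf$table
    out <- data.frame(gene = rownames(mat), log2fc = tab$logFC,
                      pvalue = tab$PValue, stringsAsFactors = FALSE)
  } else {
    cpre <- rowSums(mat[, grp == pre, drop = FALSE])
    cpost <- rowSums(mat[, grp == post, drop = FALSE])
    tot_pre <- sum(cpre); tot_post <- sum(cpost)
    if (tot_pre <= 0 || tot_post <= 0) stop("zero library total")
    share <- tot_post / (tot_pre + tot_post)
    out <- data.frame(
      gene = rownames(mat),
      log2fc = log2((cpost * 1e6 / tot_post + 1) / (cpre * 1e6 / tot_pre + 1)),
      pvalue = vapply(seq_along(cpre), function(i)
        .binom_p2(cpost[i], cpre[i] + cpost[i], share), numeric(1)),
      stringsAsFactors = FALSE)
  }
  out$fdr <- stats::p.adjust(out$pvalue, method = "BH")
  out$status <- "unchanged"
  sig <- out$fdr <= alpha & abs(out$log2fc) >= min_lfc
  out$status[sig & out$log2fc > 0] <- "up"
  out$status[sig & out$log2fc < 0] <- "down"
  rownames(out) <- NULL
  out
}

#' Intersect named DEG sets across datasets
#'
#' @param sets named list of gene-id vectors (>= 2 sets).
#' @return list with `consistent` (genes in every set, sorted) and
#'   `membership` (gene x set logical table over the union, deterministic
#'   order). Order- and duplication-invariant.
#' @export
intersect_deg_sets <- function(sets) {
  if (length(sets) < 2) stop("need at least 2 sets")
  if (is.null(names(sets)) || any(!nzchar(names(sets))) ||
      anyDuplicated(names(sets)))
    stop("sets must have unique non-empty names")
  sets <- lapply(sets, function(s) sort(unique(as.character(s))))
  all_genes <- sort(unique(unlist(sets)))
  membership <- as.data.frame(
    lapply(sets, function(s) all_genes %in% s), optional = TRUE)
  names(membership) <- names(sets)
  rownames(membership) <- all_genes
  consistent <- all_genes[rowSums(as.matrix(membership)) == length(sets)]
  list(consistent = consistent, membership = membership)
}

#' Flag genes with promoter-proximal CTCF binding
#'
#' @param prom_windows [promoter_windows()] output (gene ids in `name`).
#' @param ctcf_peaks interval table of CTCF peaks.
#' @param slack overlap tolerance in bp.
#' @return named logical vector per gene, with the flagged fraction as
#'   `attr(, "fraction")`.
#' @export
flag_promoter_ctcf <- function(prom_windows, ctcf_peaks, slack = 0) {
  flag <- overlaps_any(prom_windows, ctcf_peaks, slack = slack)
  names(flag) <- prom_windows$name
  attr(flag, "fraction") <- if (length(flag)) mean(flag) else NA_real_
  flag
}

# CPM-scale per-condition gene means; invariant to uniform depth scaling of
# any condition's libraries.
.condition_means <- function(counts, design, conditions) {
  depth <- colSums(counts)
  if (any(depth <= 0)) stop("zero library total")
  cpm <- sweep(counts, 2, depth, "/") * 1e6
  out <- do.call(cbind, lapply(conditions, function(cond) {
    s <- design$sample[design$condition == cond]
    if (!length(s)) stop("missing condition: ", cond)
    rowMeans(cpm[, s, drop = FALSE])
  }))
  dimnames(out) <- list(rownames(counts), conditions)
  out
}

#' Classify wt/mut rescue patterns of IAA-responsive genes
#'
#' A gene counts as rescued under a condition when its mean expression
#' returns to within `tolerance` log2 units of the untreated baseline.
#' Rescue by the loop-deficient mutant implies the gene does not need CTCF
#' loops: `loop_independent` = rescued under mut (regardless of wt);
#' `loop_dependent` = rescued under wt but not mut; `not_rescued` =
#' neither.
#'
#' @param counts genes x samples count matrix.
#' @param design data.frame `sample`, `condition`.
#' @param deg_genes genes to classify (the IAA-responsive set).
#' @param tolerance log2 tolerance around baseline (default 0.5).
#' @param conditions named list/vector with entries `ctrl`, `iaa`, `wt`,
#'   `mut` giving the condition names.
#' @return data.frame `gene`, `log2_iaa`, `log2_wt`, `log2_mut`,
#'   `rescue_class`.
#' @export
classify_rescue <- function(counts, design, deg_genes, tolerance = 0.5,
                            conditions = c(ctrl = "untreated", iaa = "IAA",
                                           wt = "wt_IAA", mut = "mut_IAA")) {
  need <- c("ctrl", "iaa", "wt", "mut")
  if (!all(need %in% names(conditions)))
    stop("conditions must name: ", paste(need, collapse = ", "))
  mu <- .condition_means(counts, design, unlist(conditions[need]))
  colnames(mu) <- need
  genes <- intersect(deg_genes, rownames(mu))
  mu <- mu[genes, , drop = FALSE]
  eps <- 1e-9
  l2 <- function(cond) log2((mu[, cond] + eps) / (mu[, "ctrl"] + eps))
  li <- l2("iaa"); lw <- l2("wt"); lm <- l2("mut")
  rescued_wt <- abs(lw) <= tolerance
  rescued_mut <- abs(lm) <= tolerance
  cls <- ifelse(rescued_mut, "loop_independent",
                ifelse(rescued_wt, "loop_dependent", "not_rescued"))
  data.frame(gene = genes, log2_iaa = li, log2_wt = lw, log2_mut = lm,
             rescue_class = cls, row.names = NULL, stringsAsFactors = FALSE)
}

#' Exclude globally IAA-responsive genes
#'
#' Genes deviating from the untreated baseline in the same direction beyond
#' `tolerance` log2 units in every IAA-containing condition (IAA alone and
#' both rescue conditions) respond to auxin itself rather than to CTCF loss
#' and are removed before rescue classification.
#'
#' @inheritParams classify_rescue
#' @return character vector of excluded gene ids.
#' @export
iaa_responsive_genes <- function(counts, design, tolerance = 0.5,
                                 conditions = c(ctrl = "untreated",
                                                iaa = "IAA", wt = "wt_IAA",
                                                mut = "mut_IAA")) {
  mu <- .condition_means(counts, design,
                         unlist(conditions[c("ctrl", "iaa", "wt", "mut")]))
  colnames(mu) <- c("ctrl", "iaa", "wt", "mut")
  eps <- 1e-9
  l2 <- log2((mu[, c("iaa", "wt", "mut")] + eps) / (mu[, "ctrl"] + eps))
  down <- rowSums(l2 < -tolerance) == 3
  up <- rowSums(l2 > tolerance) == 3
  rownames(mu)[down | up]
}

#' Genes associated with differential EP/PP interactions
#'
#' A gene is associated with an interaction when either anchor of the
#' interaction overlaps the gene's promoter window. Restricted to
#' interactions of the given functional classes and differential call.
#'
#' @param diff_results [call_differential()] output on interactions.
#' @param interactions the canonical interaction table.
#' @param itypes [classify_interaction_types()] output.
#' @param prom_windows [promoter_windows()] output.
#' @param classes functional classes to keep (default EP and PP).
#' @param call differential call to keep (default `down`).
#' @param slack overlap tolerance in bp.
#' @return character vector of gene ids.
#' @export
genes_with_diff_interactions <- function(diff_results, interactions, itypes,
                                         prom_windows,
                                         classes = c("EP", "PP"),
                                         call = "down", slack = 0) {
  ids <- diff_results$id[diff_results$call %in% call]
  ids <- intersect(ids, itypes$id[itypes$class %in% classes])
  sel <- interactions[interactions$id %in% ids, , drop = FALSE]
  if (!nrow(sel)) return(character(0))
  anchors <- loop_anchors(sel)
  hits <- .overlap_hits(anchors, prom_windows, slack = slack)
  sort(unique(prom_windows$name[hits$subject]))
}

#' Partition downregulated genes by regulatory mechanism
#'
#' The three-way logic of the integrative analysis: a downregulated gene
#' with promoter CTCF binding but no concomitant loss of EP/PP interactions
#' is a loop-independent candidate; with both, cooperative; interaction
#' loss without promoter CTCF, loop-only; neither, unexplained.
#'
#' @param deg_down character vector of downregulated gene ids.
#' @param promoter_ctcf named logical vector ([flag_promoter_ctcf()]).
#' @param genes_down_interactions gene ids associated with downregulated
#'   EP/PP interactions.
#' @return data.frame `gene`, `mechanism` in `loop_independent_candidate`,
#'   `cooperative`, `loop_only`, `neither`; a true partition of `deg_down`.
#' @export
partition_deg_by_mechanism <- function(deg_down, promoter_ctcf,
                                       genes_down_interactions) {
  deg_down <- sort(unique(as.character(deg_down)))
  ctcf <- deg_down %in% names(promoter_ctcf)[promoter_ctcf]
  loopy <- deg_down %in% genes_down_interactions
  mech <- ifelse(ctcf & !loopy, "loop_independent_candidate",
                 ifelse(ctcf & loopy, "cooperative",
                        ifelse(loopy, "loop_only", "neither")))
  data.frame(gene = deg_down, mechanism = mech, stringsAsFactors = FALSE)
}

#' Render a printed fraction as a percentage
#'
#' Round-half-up to `decimals`, the arithmetic behind every printed
#' percentage in the reports (e.g. 106/128 at one decimal is 82.8).
#'
#' @param numerator,denominator non-negative counts; denominator > 0.
#' @param decimals digits after the point (default 1).
#' @return list with `value` (numeric percentage) and `label`
#'   (`"82.8% (106/128)"`).
#' @export
percent_report <- function(numerator, denominator, decimals = 1) {
  if (denominator <= 0) stop("denominator must be > 0")
  raw <- 100 * numerator / denominator
  scale <- 10^decimals
  value <- floor(raw * scale + 0.5) / scale
  list(value = value,
       label = sprintf(paste0("%.", decimals, "f%% (%s/%s)"), value,
                       format(numerator, scientific = FALSE, trim = TRUE),
                       format(denominator, scientific = FALSE, trim = TRUE)))
}
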