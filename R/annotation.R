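# Anchor and interaction typing: CTCF (C), enhancer (E), promoter (P) and
# their composites (CE, CP, EP, CEP), plus the descriptive genomics used to
# contrast looping and non-looping H3K27ac loci.

.composite_label <- function(ctcf, enhancer, promoter) {
  lab <- paste0(ifelse(ctcf, "C", ""), ifelse(enhancer, "E", ""),
                ifelse(promoter, "P", ""))
  ifelse(nzchar(lab), lab, "none")
}

#' Label anchors by overlap with CTCF, enhancer and promoter annotations
#'
#' @param anchors interval table (typically [loop_anchors()] output).
#' @param ctcf_peaks,enhancers,promoters interval tables; any may be empty.
#' @param slack overlap tolerance in bp (default 0; recorded in the result).
#' @return `anchors` with logical `ctcf`, `enhancer`, `promoter` columns and
#'   a `composite` rendering (C before E before P, e.g. `CP`).
#' @export
label_anchors <- function(anchors, ctcf_peaks, enhancers, promoters,
                          slack = 0) {
  check_intervals(anchors)
  anchors$ctcf <- overlaps_any(anchors, ctcf_peaks, slack = slack)
  anchors$enhancer <- overlaps_any(anchors, enhancers, slack = slack)
  anchors$promoter <- overlaps_any(anchors, promoters, slack = slack)
  anchors$composite <- .composite_label(anchors$ctcf, anchors$enhancer,
                                        anchors$promoter)
  attr(anchors, "slack") <- slack
  anchors
}

#' Classify interactions by the functional identity of their anchors
#'
#' The functional letter of an anchor is `P` when it overlaps a promoter
#' (promoter takes precedence over enhancer), `E` when enhancer-only, `X`
#' otherwise. The interaction class is the unordered letter pair (`PP`,
#' `EP`, `EE`, `PX`, `EX`, `XX`) - swapping anchors never changes it. CTCF
#' co-binding is kept in separate structural columns rather than folded into
#' the functional class.
#'
#' @param x canonical loop table.
#' @param anchor_labels [label_anchors()] output on `loop_anchors(x)`.
#' @return data.frame `id`, `class`, `ctcf_left`, `ctcf_right`.
#' @export
classify_interaction_types <- function(x, anchor_labels) {
  if (!nrow(x))
    return(data.frame(id = character(), class = character(),
                      ctcf_left = logical(), ctcf_right = logical()))
  key <- paste(anchor_labels$id, anchor_labels$side)
  iL <- match(paste(x$id, "L"), key)
  iR <- match(paste(x$id, "R"), key)
  if (any(is.na(iL)) || any(is.na(iR)))
    stop("anchor labels missing for some loops")
  letter <- function(i) ifelse(anchor_labels$promoter[i], "P",
                               ifelse(anchor_labels$enhancer[i], "E", "X"))
  a <- letter(iL); b <- letter(iR)
  lo <- pmin(a, b); hi <- pmax(a, b)
  data.frame(id = x$id, class = paste0(lo, hi),
             ctcf_left = anchor_labels$ctcf[iL],
             ctcf_right = anchor_labels$ctcf[iR],
             stringsAsFactors = FALSE)
}

#' Strand-aware promoter windows around TSSs
#'
#' For a `+` strand gene the window is `[tss - upstream, tss + downstream)`;
#' for `-` strand genes the orientation flips. Windows are clipped to
#' chromosome bounds when a genome is supplied.
#'
#' @param genes data.frame with `gene_id`, `chrom`, `tss`, `strand`.
#' @param upstream,downstream extents in bp (default 1,000 each,
#'   i.e. -1000..+1000 around the TSS).
#' @param chrom_sizes optional named genome vector for clipping.
#' @return interval table with `name` = gene id and `strand`.
#' @export
promoter_windows <- function(genes, upstream = 1000, downstream = 1000,
                             chrom_sizes = NULL) {
  need <- c("gene_id", "chrom", "tss", "strand")
  miss <- setdiff(need, names(genes))
  if (length(miss))
    stop("gene models lack columns: ", paste(miss, collapse = ", "))
  if (any(is.na(genes$strand)) || !all(genes$strand %in% c("+", "-")))
    stop("gene models need explicit +/- strand")
  plus <- genes$strand == "+"
  s <- ifelse(plus, genes$tss - upstream, genes$tss - downstream)
  e <- ifelse(plus, genes$tss + downstream, genes$tss + upstream)
  out <- data.frame(chrom = genes$chrom, start = pmax(0, s), end = e,
                    name = genes$gene_id, strand = genes$strand,
                    stringsAsFactors = FALSE)
  if (!is.null(chrom_sizes)) out <- clip_intervals(out, chrom_sizes, warn = FALSE)
  check_intervals(out, stranded = TRUE)
  out
}

#' Fraction of sites participating in chromatin interactions
#'
#' A site is "looping" when it overlaps any interaction anchor.
#'
#' @param sites interval table (e.g. H3K27ac loci).
#' @param interactions canonical loop table.
#' @param slack overlap tolerance in bp.
#' @return list with `n_looping`, `n_total`, `fraction`.
#' @export
looping_fraction <- function(sites, interactions, slack = 0) {
  anchors <- loop_anchors(interactions)
  hit <- overlaps_any(sites, anchors, slack = slack)
  list(n_looping = sum(hit), n_total = nrow(sites),
       fraction = if (nrow(sites)) sum(hit) / nrow(sites) else NA_real_,
       looping = hit)
}
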