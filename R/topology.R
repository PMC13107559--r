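# Spatial classification of regulatory (H3K27ac) interactions against a set
# of structural (CTCF) loops. Five pairwise relations are defined between a
# regulatory loop h and a structural loop c with span S (midpoint span by
# default):
#
#   contain  - h's anchor midpoints bracket S; sharing an anchor with c counts
#              as containment at that edge. Subtype = number of
#              corresponding-side shared anchors: 0 -> I, 1 -> II, 2 -> III
#              (III interactions coincide with the CTCF loop itself).
#   cross    - exactly one h midpoint strictly inside S, the other strictly
#              outside, and not contain.
#   inside   - both h midpoints strictly inside S, no shared anchor.
#   neighbor - exactly one h anchor shared with either c anchor, the other h
#              midpoint strictly outside S (h extends away from the loop body).
#   none     - anything else; an interaction with no relation to any
#              structural loop is categorized "outside".
#
# "Shared" means the two anchor intervals overlap within `slack` bp.

# Vectorized relation evaluation over parallel vectors describing (h, c)
# pairs. Returns a data.frame with relation, subtype and shared-side flags.
.relate_vec <- function(h1s, h1e, h2s, h2e, c1s, c1e, c2s, c2e,
                        slack = 0, span_mode = "midpoint") {
  ov <- function(as, ae, bs, be) (as - slack < be) & (bs - slack < ae)
  if (span_mode == "outer") {
    S0 <- c1s; S1 <- c2e
  } else {
    S0 <- floor((c1s + c1e) / 2); S1 <- floor((c2s + c2e) / 2)
  }
  hm1 <- floor((h1s + h1e) / 2)
  hm2 <- floor((h2s + h2e) / 2)
  s_LL <- ov(h1s, h1e, c1s, c1e)
  s_RR <- ov(h2s, h2e, c2s, c2e)
  s_LR <- ov(h1s, h1e, c2s, c2e)
  s_RL <- ov(h2s, h2e, c1s, c1e)
  contain <- ((hm1 <= S0) | s_LL) & ((hm2 >= S1) | s_RR)
  subtype <- ifelse(contain, s_LL + s_RR, NA_integer_)
  in1 <- hm1 > S0 & hm1 < S1; in2 <- hm2 > S0 & hm2 < S1
  out1 <- hm1 < S0 | hm1 > S1; out2 <- hm2 < S0 | hm2 > S1
  cross <- !contain & ((in1 & out2) | (in2 & out1))
  a1_shared <- s_LL | s_LR
  a2_shared <- s_RL | s_RR
  nshared <- a1_shared + a2_shared
  inside <- !contain & !cross & in1 & in2 & nshared == 0
  neighbor <- !contain & !cross & !inside & nshared == 1 &
    ((a1_shared & out2) | (a2_shared & out1))
  relation <- rep("none", length(hm1))
  relation[neighbor] <- "neighbor"
  relation[inside] <- "inside"
  relation[cross] <- "cross"
  relation[contain] <- "contain"
  data.frame(relation = relation, contain_subtype = subtype,
             shared_left = s_LL, shared_right = s_RR,
             stringsAsFactors = FALSE)
}

#' Relate one regulatory interaction to one structural loop
#'
#' @param h,c single-row canonical loop tables on the same chromosome.
#' @param slack anchor-sharing tolerance in bp.
#' @param span_mode `"midpoint"` (default) or `"outer"` span of `c`.
#' @return one-row data.frame with `relation` (`contain`, `cross`,
#'   `neighbor`, `inside` or `none`), `contain_subtype` (1/2/3 when the
#'   relation is contain, else `NA`), and which anchors are shared.
#' @export
relate_pair <- function(h, c, slack = 0, span_mode = c("midpoint", "outer")) {
  span_mode <- match.arg(span_mode)
  stopifnot(nrow(h) == 1, nrow(c) == 1)
  if (h$chrom != c$chrom)
    return(data.frame(relation = "none", contain_subtype = NA_integer_,
                      shared_left = FALSE, shared_right = FALSE,
                      stringsAsFactors = FALSE))
  r <- .relate_vec(h$start1, h$end1, h$start2, h$end2,
                   c$start1, c$end1, c$start2, c$end2,
                   slack = slack, span_mode = span_mode)
  if (r$relation == "contain") r$contain_subtype <- r$contain_subtype + 1L
  r
}

# Candidate (h, c) pairs via an interval index on outer spans. The h window
# is padded by the interaction's own span length plus slack, which cannot
# miss any qualifying c (equivalence to the exhaustive scan is asserted in
# the test suite).
.candidate_pairs <- function(h, ctcf, slack = 0) {
  hw <- data.frame(chrom = h$chrom,
                   start = pmax(0, h$start1 - (h$end2 - h$start1) - slack - 1),
                   end = h$end2 + (h$end2 - h$start1) + slack + 1,
                   stringsAsFactors = FALSE)
  cw <- data.frame(chrom = ctcf$chrom, start = ctcf$start1, end = ctcf$end2,
                   stringsAsFactors = FALSE)
  .overlap_hits(hw, cw, slack = 0)
}

#' Full relation table between interactions and structural loops
#'
#' One row per (interaction, CTCF loop) pair with a non-`none` relation.
#' Candidate pairs are retrieved with an interval index; set
#' `exhaustive = TRUE` to force evaluation of every pair.
#'
#' @param h3k canonical regulatory loop table.
#' @param ctcf canonical structural loop table with `strength`.
#' @param slack anchor-sharing tolerance in bp.
#' @param span_mode structural span convention.
#' @param exhaustive evaluate all pairs without the index.
#' @return data.frame `id`, `ctcf_id`, `relation`, `contain_subtype`
#'   (1/2/3), `shared_left`, `shared_right`, `ctcf_strength`.
#' @export
relate_all <- function(h3k, ctcf, slack = 0,
                       span_mode = c("midpoint", "outer"),
                       exhaustive = FALSE) {
  span_mode <- match.arg(span_mode)
  empty <- data.frame(id = character(), ctcf_id = character(),
                      relation = character(), contain_subtype = integer(),
                      shared_left = logical(), shared_right = logical(),
                      ctcf_strength = numeric(), stringsAsFactors = FALSE)
  if (!nrow(h3k) || !nrow(ctcf)) return(empty)
  if (exhaustive) {
    pairs <- expand.grid(query = seq_len(nrow(h3k)),
                         subject = seq_len(nrow(ctcf)))
    pairs <- pairs[h3k$chrom[pairs$query] == ctcf$chrom[pairs$subject], ,
                   drop = FALSE]
  } else {
    pairs <- .candidate_pairs(h3k, ctcf, slack = slack)
  }
  if (!nrow(pairs)) return(empty)
  qi <- pairs$query; si <- pairs$subject
  r <- .relate_vec(h3k$start1[qi], h3k$end1[qi], h3k$start2[qi], h3k$end2[qi],
                   ctcf$start1[si], ctcf$end1[si], ctcf$start2[si],
                   ctcf$end2[si], slack = slack, span_mode = span_mode)
  keep <- r$relation != "none"
  out <- data.frame(id = h3k$id[qi][keep], ctcf_id = ctcf$id[si][keep],
                    relation = r$relation[keep],
                    contain_subtype = r$contain_subtype[keep] + 1L,
                    shared_left = r$shared_left[keep],
                    shared_right = r$shared_right[keep],
                    ctcf_strength = ctcf$strength[si][keep],
                    stringsAsFactors = FALSE)
  out <- out[order(match(out$id, h3k$id), match(out$ctcf_id, ctcf$id)), ,
             drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Topology categories
#'
#' @return character vector of the composite category vocabulary.
#' @export
topology_categories <- function() {
  c("contain", "cross", "contain_and_cross", "neighbor", "inside",
    "outside", "other_composite")
}

#' Classify each interaction's topology against the structural loop set
#'
#' Collects all pairwise relations per interaction and derives the composite
#' category: exactly one relation type present gives that type; contain and
#' cross (and nothing else) gives `contain_and_cross`; no relations gives
#' `outside`; any other mixture is reported as `other_composite` rather than
#' forced into a scheme the underlying figures do not define. The contain
#' subtype reported per interaction is the maximum shared-anchor subtype
#' among its contain relations (III > II > I).
#'
#' @inheritParams relate_all
#' @param relations optional precomputed [relate_all()] table.
#' @return data.frame with one row per interaction: `id`, `category`,
#'   `contain_subtype`, relation counts, `max_contain_strength`,
#'   `max_cross_strength`; the relation table is attached as
#'   `attr(, "relations")` and the predicate configuration as
#'   `attr(, "config")`.
#' @export
classify_topology <- function(h3k, ctcf, slack = 0,
                              span_mode = c("midpoint", "outer"),
                              exhaustive = FALSE, relations = NULL) {
  span_mode <- match.arg(span_mode)
  if (is.null(relations))
    relations <- relate_all(h3k, ctcf, slack = slack, span_mode = span_mode,
                            exhaustive = exhaustive)
  nh <- nrow(h3k)
  out <- data.frame(id = h3k$id,
                    category = rep("outside", nh),
                    contain_subtype = rep(NA_integer_, nh),
                    n_contain = rep(0L, nh), n_cross = rep(0L, nh),
                    n_neighbor = rep(0L, nh), n_inside = rep(0L, nh),
                    max_contain_strength = rep(NA_real_, nh),
                    max_cross_strength = rep(NA_real_, nh),
                    stringsAsFactors = FALSE)
  if (nrow(relations)) {
    sp <- split(relations, factor(relations$id, levels = h3k$id))
    for (i in seq_along(sp)) {
      rel <- sp[[i]]
      if (!nrow(rel)) next
      types <- unique(rel$relation)
      cat <- if (setequal(types, c("contain", "cross"))) "contain_and_cross"
      else if (length(types) == 1) types
      else "other_composite"
      out$category[i] <- cat
      out$n_contain[i] <- sum(rel$relation == "contain")
      out$n_cross[i] <- sum(rel$relation == "cross")
      out$n_neighbor[i] <- sum(rel$relation == "neighbor")
      out$n_inside[i] <- sum(rel$relation == "inside")
      if (out$n_contain[i] > 0) {
        ci <- rel$relation == "contain"
        out$contain_subtype[i] <- max(rel$contain_subtype[ci])
        out$max_contain_strength[i] <- max(rel$ctcf_strength[ci])
      }
      if (out$n_cross[i] > 0)
        out$max_cross_strength[i] <- max(rel$ctcf_strength[rel$relation == "cross"])
    }
  }
  attr(out, "relations") <- relations
  attr(out, "config") <- list(slack = slack, span_mode = span_mode)
  out
}

#' Category distribution table
#'
#' @param labels [classify_topology()] output.
#' @return data.frame `category`, `count`, `percent`; counts partition the
#'   input and percents sum to 100 up to rounding. Empty input yields an
#'   empty table.
#' @export
category_distribution <- function(labels) {
  if (!nrow(labels))
    return(data.frame(category = character(), count = integer(),
                      percent = numeric(), stringsAsFactors = FALSE))
  lev <- topology_categories()
  counts <- table(factor(labels$category, levels = lev))
  counts <- counts[counts > 0]
  data.frame(category = names(counts), count = as.integer(counts),
             percent = 100 * as.integer(counts) / nrow(labels),
             stringsAsFactors = FALSE, row.names = NULL)
}

#' H3K27ac-solo anchors of contain-type-II interactions
#'
#' A contain-II interaction shares exactly one anchor with its CTCF loop;
#' the other, CTCF-free ("solo") anchor is the one this report emits,
#' optionally joined to anchor annotation to show its regulatory identity.
#'
#' @param labels [classify_topology()] output (with attached relations).
#' @param h3k the regulatory loop table that was classified.
#' @param anchor_labels optional [label_anchors()] output on
#'   `loop_anchors(h3k)` to annotate the solo anchors.
#' @return interval table of solo anchors with `id`, `side`, and any
#'   annotation columns. Contain-III interactions contribute nothing by
#'   definition.
#' @export
solo_anchor_report <- function(labels, h3k, anchor_labels = NULL) {
  relations <- attr(labels, "relations")
  if (is.null(relations)) stop("labels must carry the relation table")
  keep <- labels$id[labels$category %in% c("contain", "contain_and_cross") &
                      !is.na(labels$contain_subtype) &
                      labels$contain_subtype == 2L]
  rel <- relations[relations$id %in% keep & relations$relation == "contain" &
                     relations$contain_subtype == 2L, , drop = FALSE]
  rel <- rel[!duplicated(rel$id), , drop = FALSE]
  if (!nrow(rel))
    return(data.frame(chrom = character(), start = numeric(),
                      end = numeric(), id = character(), side = character()))
  idx <- match(rel$id, h3k$id)
  solo_right <- rel$shared_left
  out <- data.frame(
    chrom = h3k$chrom[idx],
    start = ifelse(solo_right, h3k$start2[idx], h3k$start1[idx]),
    end = ifelse(solo_right, h3k$end2[idx], h3k$end1[idx]),
    id = rel$id, side = ifelse(solo_right, "R", "L"),
    stringsAsFactors = FALSE)
  if (!is.null(anchor_labels)) {
    key <- paste(anchor_labels$id, anchor_labels$side)
    m <- match(paste(out$id, out$side), key)
    for (col in c("ctcf", "enhancer", "promoter", "composite"))
      if (!is.null(anchor_labels[[col]])) out[[col]] <- anchor_labels[[col]][m]
  }
  out
}
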