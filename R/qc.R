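# Interaction-call QC: the three-step chain applied to raw loop calls before
# any classification - drop short-range contacts, drop low-count loops, and
# merge loops that connect the same pair of annotated genomic elements.
# Thresholds are deliberately mandatory-by-default arguments: results are
# never silently threshold-dependent.

#' Remove short-range loops
#'
#' Retains loops whose anchor-midpoint distance is at least `min_distance`.
#'
#' @param x canonical loop table.
#' @param min_distance minimum midpoint distance in bp (default 10 kb).
#' @return filtered loop table; the number removed is attached as
#'   `attr(, "n_removed")`.
#' @export
filter_short_range <- function(x, min_distance = 10000) {
  if (min_distance < 0) stop("min_distance must be >= 0")
  keep <- loop_distance(x) >= min_distance
  out <- x[keep, , drop = FALSE]
  attr(out, "n_removed") <- sum(!keep)
  out
}

#' Remove low-count loops
#'
#' Retains loops whose contact counts satisfy `min_count` under the chosen
#' rule: `max` (default) requires the maximum across conditions to reach the
#' threshold, `any`/`all` require at least one / every condition to.
#'
#' @param x canonical loop table with `count_<condition>` columns.
#' @param min_count minimum contact count (default 4).
#' @param rule aggregation rule across conditions.
#' @param conditions conditions to consider (default: all present).
#' @return filtered loop table with `attr(, "n_removed")`.
#' @export
filter_low_count <- function(x, min_count = 4, rule = c("max", "any", "all"),
                             conditions = NULL) {
  rule <- match.arg(rule)
  if (min_count < 0) stop("min_count must be >= 0")
  if (is.null(conditions)) conditions <- loop_conditions(x)
  missing_cond <- setdiff(conditions, loop_conditions(x))
  if (length(missing_cond))
    stop("unknown condition: ", paste(missing_cond, collapse = ", "))
  if (!length(conditions) || !nrow(x)) {
    attr(x, "n_removed") <- 0L
    return(x)
  }
  cm <- as.matrix(x[paste0("count_", conditions)])
  keep <- switch(rule,
                 max = apply(cm, 1, max) >= min_count,
                 any = apply(cm, 1, function(v) any(v >= min_count)),
                 all = apply(cm, 1, function(v) all(v >= min_count)))
  out <- x[keep, , drop = FALSE]
  attr(out, "n_removed") <- sum(!keep)
  out
}

# Assign each anchor to at most one element: midpoint containment first,
# else nearest element midpoint within `max_gap`; NA when unassignable.
.assign_elements <- function(anchors, elements, max_gap = 2500) {
  if (is.null(elements$name)) stop("elements need a 'name' column")
  n <- nrow(anchors)
  out <- rep(NA_character_, n)
  mids <- interval_midpoints(anchors)
  emids <- interval_midpoints(elements)
  for (ch in unique(anchors$chrom)) {
    ai <- which(anchors$chrom == ch)
    ei <- which(elements$chrom == ch)
    if (!length(ei)) next
    for (i in ai) {
      m <- mids[i]
      inside <- ei[elements$start[ei] <= m & m < elements$end[ei]]
      cand <- if (length(inside)) inside else {
        d <- abs(emids[ei] - m)
        if (min(d) <= max_gap) ei[which.min(d)] else integer(0)
      }
      if (length(cand)) {
        d <- abs(emids[cand] - m)
        out[i] <- elements$name[cand[which.min(d)]]
      }
    }
  }
  out
}

#' Merge loops connecting identical element pairs
#'
#' Anchors are assigned to annotated elements (midpoint containment, falling
#' back to the nearest element within `max_gap`); loops whose ordered
#' element pair is identical are collapsed into one record with counts
#' summed per condition and anchors replaced by the element spans. Loops
#' with an unassignable anchor are exempt from merging. Total contact count
#' per condition is conserved exactly.
#'
#' @param x canonical loop table.
#' @param elements interval table with a `name` column (promoters,
#'   enhancers, ... - any annotated genomic elements).
#' @param max_gap fallback assignment distance in bp.
#' @return loop table; merged records carry the source ids in a
#'   `merged_from` column.
#' @export
merge_identical_element_loops <- function(x, elements, max_gap = 2500) {
  if (!nrow(x)) {
    x$merged_from <- character(0)
    attr(x, "n_removed") <- 0L
    return(x)
  }
  a <- loop_anchors(x)
  assign <- .assign_elements(a, elements, max_gap = max_gap)
  elemL <- assign[seq_len(nrow(x))]
  elemR <- assign[nrow(x) + seq_len(nrow(x))]
  key <- ifelse(is.na(elemL) | is.na(elemR),
                paste0("__solo__", x$id), paste(elemL, elemR, sep = "\r"))
  conds <- loop_conditions(x)
  groups <- split(seq_len(nrow(x)), key)
  rows <- lapply(groups, function(idx) {
    first <- idx[1]
    rec <- x[first, , drop = FALSE]
    rec$merged_from <- paste(x$id[idx], collapse = ",")
    if (length(idx) > 1) {
      for (cond in conds) {
        col <- paste0("count_", cond)
        rec[[col]] <- sum(x[[col]][idx])
      }
      rec$strength <- sum(x$strength[idx])
      eL <- elements[match(elemL[first], elements$name), ]
      eR <- elements[match(elemR[first], elements$name), ]
      rec$start1 <- eL$start; rec$end1 <- eL$end
      rec$start2 <- eR$start; rec$end2 <- eR$end
      if (rec$start1 > rec$start2) {
        tmp <- c(rec$start1, rec$end1)
        rec$start1 <- rec$start2; rec$end1 <- rec$end2
        rec$start2 <- tmp[1]; rec$end2 <- tmp[2]
      }
    }
    rec
  })
  out <- do.call(rbind, rows)
  out <- out[order(match(out$id, x$id)), , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "n_removed") <- nrow(x) - nrow(out)
  out
}
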