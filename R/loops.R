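#' Construct a loop table
#'
#' A loop is an ordered pair of anchor intervals on one chromosome plus
#' per-condition contact counts and a normalized strength score. Loop tables
#' carry one `count_<condition>` column per configured condition; the same
#' structure holds both CTCF loops and H3K27ac-mediated interactions.
#'
#' @param id unique loop identifiers.
#' @param chrom chromosome (one per loop; trans pairs are not representable).
#' @param start1,end1 left anchor, 0-based half-open.
#' @param start2,end2 right anchor.
#' @param strength non-negative normalized score.
#' @param counts named list / data.frame of per-condition non-negative
#'   integer counts, one element per condition.
#' @return canonical loop data.frame.
#' @export
loops <- function(id, chrom, start1, end1, start2, end2, strength = 0,
                  counts = list()) {
  n <- length(start1)
  rep_n <- function(v) if (n) rep(v, length.out = n) else v[0]
  x <- data.frame(id = rep_n(as.character(id)), chrom = rep_n(as.character(chrom)),
                  start1 = as.numeric(start1), end1 = as.numeric(end1),
                  start2 = as.numeric(start2), end2 = as.numeric(end2),
                  strength = rep_n(as.numeric(strength)),
                  stringsAsFactors = FALSE)
  for (cond in names(counts))
    x[[paste0("count_", cond)]] <- rep_n(as.numeric(counts[[cond]]))
  canonicalize_loops(x)
}

#' Condition names carried by a loop or feature table
#'
#' @param x data.frame with `count_<condition>` columns.
#' @return character vector of condition names.
#' @export
loop_conditions <- function(x) {
  sub("^count_", "", grep("^count_", names(x), value = TRUE))
}

#' Canonicalize loops
#'
#' Orders the two anchors left-to-right by start and validates the loop
#' invariants. Idempotent; ids are preserved. Inter-chromosomal (trans)
#' input is rejected: all topology classes are defined in cis only.
#'
#' @param x loop table, possibly with unordered anchors; may carry a
#'   `chrom2` column from BEDPE input (must equal `chrom`).
#' @return canonical loop table.
#' @export
canonicalize_loops <- function(x) {
  stopifnot(is.data.frame(x))
  need <- c("id", "chrom", "start1", "end1", "start2", "end2")
  miss <- setdiff(need, names(x))
  if (length(miss)) stop("loop table lacks columns: ", paste(miss, collapse = ", "))
  if ("chrom2" %in% names(x)) {
    if (nrow(x) && any(x$chrom != x$chrom2))
      stop("trans interaction: anchors on different chromosomes are unsupported")
    x$chrom2 <- NULL
  }
  if (!nrow(x)) return(x)
  if (anyDuplicated(x$id)) stop("loop ids must be unique")
  if (any(x$start1 < 0 | x$start2 < 0)) stop("anchor start must be >= 0")
  if (any(x$end1 <= x$start1 | x$end2 <= x$start2))
    stop("anchor end must be > start")
  swap <- x$start1 > x$start2 | (x$start1 == x$start2 & x$end1 > x$end2)
  if (any(swap)) {
    s1 <- x$start1[swap]; e1 <- x$end1[swap]
    x$start1[swap] <- x$start2[swap]; x$end1[swap] <- x$end2[swap]
    x$start2[swap] <- s1; x$end2[swap] <- e1
  }
  if (any(x$end1 > x$start2))
    stop("loop anchors overlap after ordering; not a valid paired-anchor record")
  x
}

#' Loop span
#'
#' The genomic span of a loop: either the outer envelope
#' `[start1, end2)` or the interval between anchor midpoints
#' `[mid(anchor1), mid(anchor2))`. Midpoint is the package default for
#' topology tests because it does not double-count anchor width.
#'
#' @param x canonical loop table.
#' @param mode `"midpoint"` or `"outer"`.
#' @return interval table with the loop ids as `name`.
#' @export
loop_span <- function(x, mode = c("midpoint", "outer")) {
  mode <- match.arg(mode)
  if (!nrow(x))
    return(data.frame(chrom = character(), start = numeric(),
                      end = numeric(), name = character()))
  if (mode == "outer") {
    s <- x$start1; e <- x$end2
  } else {
    s <- floor((x$start1 + x$end1) / 2)
    e <- floor((x$start2 + x$end2) / 2)
  }
  data.frame(chrom = x$chrom, start = s, end = e, name = x$id,
             stringsAsFactors = FALSE)
}

#' Anchor-midpoint distance per loop
#'
#' @param x canonical loop table.
#' @return numeric vector in bp.
#' @export
loop_distance <- function(x) {
  floor((x$start2 + x$end2) / 2) - floor((x$start1 + x$end1) / 2)
}

#' Flatten loops into an anchor table
#'
#' @param x canonical loop table.
#' @return interval table with `id` and `side` (`L`/`R`) columns, two rows
#'   per loop.
#' @export
loop_anchors <- function(x) {
  if (!nrow(x))
    return(data.frame(chrom = character(), start = numeric(), end = numeric(),
                      id = character(), side = character()))
  rbind(
    data.frame(chrom = x$chrom, start = x$start1, end = x$end1,
               id = x$id, side = "L", stringsAsFactors = FALSE),
    data.frame(chrom = x$chrom, start = x$start2, end = x$end2,
               id = x$id, side = "R", stringsAsFactors = FALSE)
  )
}
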