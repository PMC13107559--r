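#' Construct a genomic interval table
#'
#' Intervals are plain data frames with 0-based half-open coordinates
#' (`start` inclusive, `end` exclusive), the native BED convention. Every
#' other structure in the package (anchors, peaks, promoter windows, ATAC
#' windows) is built on this table.
#'
#' @param chrom character vector of chromosome names.
#' @param start,end integer-like coordinate vectors, `0 <= start < end`.
#' @param strand optional strand vector in `+`, `-`, `.`.
#' @param name optional feature names.
#' @param score optional numeric scores.
#' @return data.frame with columns `chrom`, `start`, `end` and any of
#'   `strand`, `name`, `score` that were supplied.
#' @export
intervals <- function(chrom, start, end, strand = NULL, name = NULL,
                      score = NULL) {
  n <- length(start)
  rep_n <- function(v) if (n) rep(v, length.out = n) else v[0]
  x <- data.frame(chrom = rep_n(as.character(chrom)),
                  start = as.numeric(start),
                  end = as.numeric(end),
                  stringsAsFactors = FALSE)
  if (!is.null(name)) x$name <- rep_n(as.character(name))
  if (!is.null(score)) x$score <- rep_n(as.numeric(score))
  if (!is.null(strand)) x$strand <- rep_n(as.character(strand))
  check_intervals(x)
  x
}

#' Validate an interval table
#'
#' @param x data.frame with at least `chrom`, `start`, `end`.
#' @param stranded require a valid `strand` column.
#' @return `x`, invisibly, after validation.
#' @export
check_intervals <- function(x, stranded = FALSE) {
  stopifnot(is.data.frame(x))
  miss <- setdiff(c("chrom", "start", "end"), names(x))
  if (length(miss))
    stop("interval table lacks columns: ", paste(miss, collapse = ", "))
  if (nrow(x)) {
    if (any(is.na(x$chrom)) || any(!nzchar(x$chrom)))
      stop("interval chrom must be non-empty")
    if (any(x$start < 0)) stop("interval start must be >= 0")
    if (any(x$end <= x$start)) stop("interval end must be > start")
  }
  if (stranded) {
    if (is.null(x$strand)) stop("strand column required")
    if (nrow(x) && !all(x$strand %in% c("+", "-", ".")))
      stop("strand must be one of +, -, .")
  }
  invisible(x)
}

#' Interval midpoints
#'
#' @param x interval table.
#' @return numeric vector, `floor((start + end) / 2)` per row.
#' @export
interval_midpoints <- function(x) {
  floor((x$start + x$end) / 2)
}

#' Pairwise interval overlap with slack
#'
#' TRUE where interval `a[i]` expanded by `slack` bp on both sides shares at
#' least one base with `b[i]` on the same chromosome. Rows are recycled if
#' one table has a single row. The predicate is symmetric in `a` and `b`.
#'
#' @param a,b interval tables.
#' @param slack non-negative expansion in bp.
#' @return logical vector.
#' @export
intervals_overlap <- function(a, b, slack = 0) {
  if (slack < 0) stop("slack must be >= 0")
  same <- a$chrom == b$chrom
  same & (a$start - slack < b$end) & (b$start - slack < a$end)
}

# Row indices of `query` overlapping at least one `subject` interval.
# slack expands the query on both sides. Backed by IRanges per chromosome.
.overlap_hits <- function(query, subject, slack = 0) {
  if (!nrow(query) || !nrow(subject))
    return(data.frame(query = integer(), subject = integer()))
  out_q <- integer(0); out_s <- integer(0)
  for (ch in unique(query$chrom)) {
    qi <- which(query$chrom == ch)
    si <- which(subject$chrom == ch)
    if (!length(si)) next
    qr <- IRanges::IRanges(start = query$start[qi] + 1L, end = query$end[qi])
    sr <- IRanges::IRanges(start = subject$start[si] + 1L, end = subject$end[si])
    hits <- IRanges::findOverlaps(qr, sr, maxgap = slack - 1L)
    out_q <- c(out_q, qi[S4Vectors::queryHits(hits)])
    out_s <- c(out_s, si[S4Vectors::subjectHits(hits)])
  }
  o <- order(out_q, out_s)
  data.frame(query = out_q[o], subject = out_s[o])
}

#' Which query intervals overlap any subject interval
#'
#' @param query,subject interval tables.
#' @param slack expansion of the query in bp.
#' @return logical vector along `query` rows.
#' @export
overlaps_any <- function(query, subject, slack = 0) {
  hits <- .overlap_hits(query, subject, slack = slack)
  seq_len(nrow(query)) %in% hits$query
}

#' Clip intervals to chromosome bounds
#'
#' @param x interval table.
#' @param chrom_sizes named numeric vector of chromosome lengths (the genome
#'   specification used throughout the package).
#' @param warn warn when clipping occurs.
#' @return clipped interval table; rows falling entirely outside are dropped.
#' @export
clip_intervals <- function(x, chrom_sizes, warn = TRUE) {
  check_intervals(x)
  if (is.null(names(chrom_sizes)) || any(chrom_sizes <= 0))
    stop("chrom_sizes must be a named vector of positive lengths")
  unknown <- setdiff(unique(x$chrom), names(chrom_sizes))
  if (length(unknown))
    stop("chromosome not in genome: ", paste(unknown, collapse = ", "))
  lim <- unname(chrom_sizes[x$chrom])
  clipped <- x$start < 0 | x$end > lim
  if (any(clipped) && warn)
    warning(sum(clipped), " interval(s) clipped to chromosome bounds")
  x$start <- pmax(x$start, 0)
  x$end <- pmin(x$end, lim)
  x[x$end > x$start, , drop = FALSE]
}

#' Fraction of the genome covered by a union of intervals
#'
#' Overlapping spans are counted once; spans beyond chromosome ends are
#' clipped with a warning.
#'
#' @param spans interval table.
#' @param chrom_sizes named numeric vector of chromosome lengths.
#' @return fraction in `[0, 1]`.
#' @export
union_coverage <- function(spans, chrom_sizes) {
  total <- sum(as.numeric(chrom_sizes))
  if (total <= 0) stop("empty genome")
  if (!nrow(spans)) return(0)
  spans <- clip_intervals(spans, chrom_sizes)
  covered <- 0
  for (ch in unique(spans$chrom)) {
    si <- spans[spans$chrom == ch, , drop = FALSE]
    r <- IRanges::reduce(IRanges::IRanges(start = si$start + 1L, end = si$end))
    covered <- covered + sum(as.numeric(IRanges::width(r)))
  }
  covered / total
}

#' Midpoint distance to the nearest other site on the same chromosome
#'
#' @param sites interval table.
#' @return numeric vector of distances in bp; `NA` for sites alone on their
#'   chromosome.
#' @export
nearest_neighbor_distance <- function(sites) {
  check_intervals(sites)
  mids <- interval_midpoints(sites)
  out <- rep(NA_real_, nrow(sites))
  for (ch in unique(sites$chrom)) {
    idx <- which(sites$chrom == ch)
    if (length(idx) < 2) next
    m <- mids[idx]
    o <- order(m)
    ms <- m[o]
    gap_prev <- c(Inf, diff(ms))
    gap_next <- c(diff(ms), Inf)
    out[idx[o]] <- pmin(gap_prev, gap_next)
  }
  out
}
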