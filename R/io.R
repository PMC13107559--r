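# Standard-format I/O. All readers are strict: malformed lines are reported
# with their (1-based, comment-inclusive) line numbers rather than skipped.

.fmt <- function(v) format(v, scientific = FALSE, trim = TRUE, digits = 15)

.header_comment <- function(extra = NULL) {
  v <- as.character(utils::packageVersion("looptopo"))
  paste0("# looptopo v", v, if (!is.null(extra)) paste0(" ", extra))
}

.read_lines_nocomment <- function(path) {
  lines <- readLines(path)
  keep <- !grepl("^#", lines) & nzchar(lines)
  list(lines = lines[keep], lineno = which(keep))
}

.parse_coord <- function(x, what, lineno) {
  v <- suppressWarnings(as.numeric(x))
  bad <- is.na(v) | v != floor(v)
  if (any(bad))
    stop("non-integer ", what, " at line ", lineno[which(bad)[1]])
  v
}

#' Read a BEDPE file into a canonical loop table
#'
#' Expects the standard 10 BEDPE columns (`chrom1 start1 end1 chrom2 start2
#' end2 name score strand1 strand2`); any extra numeric columns are mapped,
#' in order, to per-condition contact counts named by `conditions`. The
#' `score` column is taken as the loop strength. A 6-column dialect (no
#' name/score/strands) is also accepted.
#'
#' @param path file path.
#' @param conditions condition names for extra count columns (required when
#'   extra columns are present).
#' @return canonical loop table.
#' @export
read_bedpe <- function(path, conditions = NULL) {
  rd <- .read_lines_nocomment(path)
  if (!length(rd$lines)) {
    out <- data.frame(id = character(), chrom = character(),
                      start1 = numeric(), end1 = numeric(),
                      start2 = numeric(), end2 = numeric(),
                      strength = numeric(), stringsAsFactors = FALSE)
    for (cond in conditions) out[[paste0("count_", cond)]] <- numeric()
    return(out)
  }
  fields <- strsplit(rd$lines, "\t", fixed = TRUE)
  ncol <- lengths(fields)
  if (length(unique(ncol)) != 1)
    stop("inconsistent column count at line ",
         rd$lineno[which(ncol != ncol[1])[1]])
  nc <- ncol[1]
  if (nc != 6 && nc < 10)
    stop("BEDPE needs 6 or >= 10 columns, found ", nc)
  m <- do.call(rbind, fields)
  lineno <- rd$lineno
  s1 <- .parse_coord(m[, 2], "start1", lineno)
  e1 <- .parse_coord(m[, 3], "end1", lineno)
  s2 <- .parse_coord(m[, 5], "start2", lineno)
  e2 <- .parse_coord(m[, 6], "end2", lineno)
  bad <- e1 <= s1 | e2 <= s2
  if (any(bad)) stop("end <= start at line ", lineno[which(bad)[1]])
  bad <- s1 < 0 | s2 < 0
  if (any(bad)) stop("negative coordinate at line ", lineno[which(bad)[1]])
  trans <- m[, 1] != m[, 4]
  if (any(trans))
    stop("trans interaction at line ", lineno[which(trans)[1]],
         ": anchors on different chromosomes are unsupported")
  x <- data.frame(id = if (nc >= 10) m[, 7] else paste0("loop_", seq_len(nrow(m))),
                  chrom = m[, 1],
                  start1 = s1, end1 = e1, start2 = s2, end2 = e2,
                  strength = if (nc >= 10) suppressWarnings(as.numeric(m[, 8])) else 0,
                  stringsAsFactors = FALSE)
  if (nc > 10) {
    extra <- nc - 10
    if (is.null(conditions) || length(conditions) != extra)
      stop("BEDPE has ", extra, " count column(s); supply matching 'conditions'")
    for (k in seq_len(extra)) {
      v <- suppressWarnings(as.numeric(m[, 10 + k]))
      if (any(is.na(v) | v < 0))
        stop("invalid count at line ", lineno[which(is.na(v) | v < 0)[1]])
      x[[paste0("count_", conditions[k])]] <- v
    }
  } else if (!is.null(conditions) && length(conditions)) {
    stop("conditions supplied but file carries no count columns")
  }
  canonicalize_loops(x)
}

#' Write a loop table as BEDPE
#'
#' Emits the 10 standard columns plus one count column per condition, with a
#' leading tool/provenance comment line. Round-trip stable with
#' [read_bedpe()].
#'
#' @param x canonical loop table.
#' @param path output path.
#' @param comment extra text for the header comment.
#' @export
write_bedpe <- function(x, path, comment = NULL) {
  conds <- loop_conditions(x)
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(.header_comment(comment), con)
  if (!nrow(x)) return(invisible(path))
  cols <- cbind(x$chrom, .fmt(x$start1), .fmt(x$end1),
                x$chrom, .fmt(x$start2), .fmt(x$end2),
                x$id, .fmt(x$strength),
                ".", ".")
  for (cond in conds)
    cols <- cbind(cols, .fmt(x[[paste0("count_", cond)]]))
  writeLines(apply(cols, 1, paste, collapse = "\t"), con)
  invisible(path)
}

#' Read a BED file into an interval table
#'
#' BED3 through BED6 dialects; column 7, when present, is taken as a summit
#' offset relative to `start` (used for ATAC/ChIP peak centering).
#'
#' @param path file path.
#' @return interval table with any of `name`, `score`, `strand`, `summit`.
#' @export
read_bed <- function(path) {
  rd <- .read_lines_nocomment(path)
  if (!length(rd$lines))
    return(data.frame(chrom = character(), start = numeric(),
                      end = numeric(), stringsAsFactors = FALSE))
  fields <- strsplit(rd$lines, "\t", fixed = TRUE)
  ncol <- lengths(fields)
  if (length(unique(ncol)) != 1)
    stop("inconsistent column count at line ",
         rd$lineno[which(ncol != ncol[1])[1]])
  m <- do.call(rbind, fields)
  lineno <- rd$lineno
  s <- .parse_coord(m[, 2], "start", lineno)
  e <- .parse_coord(m[, 3], "end", lineno)
  bad <- e <= s
  if (any(bad)) stop("end <= start at line ", lineno[which(bad)[1]])
  x <- data.frame(chrom = m[, 1], start = s, end = e, stringsAsFactors = FALSE)
  if (ncol[1] >= 4) x$name <- m[, 4]
  if (ncol[1] >= 5) x$score <- suppressWarnings(as.numeric(m[, 5]))
  if (ncol[1] >= 6) {
    if (!all(m[, 6] %in% c("+", "-", ".")))
      stop("invalid strand at line ",
           lineno[which(!(m[, 6] %in% c("+", "-", ".")))[1]])
    x$strand <- m[, 6]
  }
  if (ncol[1] >= 7) x$summit <- .parse_coord(m[, 7], "summit", lineno)
  check_intervals(x)
  x
}

#' Write an interval table as BED
#'
#' @param x interval table.
#' @param path output path.
#' @param comment extra text for the header comment.
#' @export
write_bed <- function(x, path, comment = NULL) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(.header_comment(comment), con)
  if (!nrow(x)) return(invisible(path))
  cols <- cbind(x$chrom, .fmt(x$start), .fmt(x$end))
  has_summit <- !is.null(x$summit)
  if (!is.null(x$name) || !is.null(x$score) || !is.null(x$strand) || has_summit)
    cols <- cbind(cols, if (is.null(x$name)) "." else x$name)
  if (!is.null(x$score) || !is.null(x$strand) || has_summit)
    cols <- cbind(cols, if (is.null(x$score)) "0" else .fmt(x$score))
  if (!is.null(x$strand) || has_summit)
    cols <- cbind(cols, if (is.null(x$strand)) "." else x$strand)
  if (has_summit)
    cols <- cbind(cols, .fmt(x$summit))
  writeLines(apply(cols, 1, paste, collapse = "\t"), con)
  invisible(path)
}

#' Write a data frame as a headered TSV with a provenance comment
#'
#' @param x data.frame.
#' @param path output path.
#' @param comment extra text for the header comment.
#' @export
write_tsv <- function(x, path, comment = NULL) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(.header_comment(comment), con)
  utils::write.table(x, con, sep = "\t", quote = FALSE, row.names = FALSE,
                     col.names = TRUE)
  invisible(path)
}

#' Read a TSV written by [write_tsv()]
#'
#' @param path file path.
#' @return data.frame.
#' @export
read_tsv <- function(path) {
  utils::read.table(path, sep = "\t", header = TRUE, comment.char = "#",
                    stringsAsFactors = FALSE, check.names = FALSE)
}
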