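#' Genomic intervals
#'
#' All coordinates in this package are 0-based, half-open `[start, end)` on a
#' named chromosome, the BED convention. SAM input (1-based) is converted at
#' the boundary by [read_alignments()]. Strand is `"+"`, `"-"` or `"."` for
#' strand-agnostic features such as windows and segments.
#'
#' @param chrom Character chromosome names.
#' @param start Integer 0-based inclusive starts.
#' @param end Integer exclusive ends.
#' @param strand `"+"`, `"-"` or `"."` (recycled).
#' @return A `data.frame` with columns `chrom`, `start`, `end`, `strand`.
#' @examples
#' gintervals("chr1", 0, 100)
#' @export
gintervals <- function(chrom, start, end, strand = ".") {
  df <- data.frame(
    chrom = as.character(chrom),
    start = as.integer(start),
    end = as.integer(end),
    strand = rep_len(as.character(strand), length(chrom)),
    stringsAsFactors = FALSE
  )
  validate_intervals(df)
  df
}

#' Validate interval invariants
#'
#' Checks `0 <= start < end`, non-empty chromosome names and a legal strand
#' vocabulary; stops with an informative error otherwise.
#'
#' @param df Interval `data.frame` (columns `chrom`, `start`, `end`, and
#'   optionally `strand`).
#' @return `df`, invisibly.
#' @export
validate_intervals <- function(df) {
  stopifnot(is.data.frame(df), all(c("chrom", "start", "end") %in% names(df)))
  if (nrow(df) == 0) return(invisible(df))
  if (any(is.na(df$chrom) | !nzchar(df$chrom)))
    stop("interval error: empty chromosome name")
  if (any(df$start < 0))
    stop("interval error: negative start coordinate")
  if (any(df$start >= df$end))
    stop("interval error: start >= end (0-based half-open intervals required)")
  if ("strand" %in% names(df) && !all(df$strand %in% c("+", "-", ".")))
    stop("interval error: strand must be one of '+', '-', '.'")
  invisible(df)
}

interval_width <- function(df) df$end - df$start

# Overlap index pairs between two 0-based half-open interval frames.
# Returns data.frame(query=, subject=) of row indices.
overlap_pairs <- function(query, subject) {
  qs <- integer(0)
  ss <- integer(0)
  for (ch in intersect(unique(query$chrom), unique(subject$chrom))) {
    qi <- which(query$chrom == ch)
    si <- which(subject$chrom == ch)
    hits <- IRanges::findOverlaps(
      IRanges::IRanges(start = query$start[qi] + 1L, end = query$end[qi]),
      IRanges::IRanges(start = subject$start[si] + 1L, end = subject$end[si])
    )
    qs <- c(qs, qi[S4Vectors::queryHits(hits)])
    ss <- c(ss, si[S4Vectors::subjectHits(hits)])
  }
  data.frame(query = qs, subject = ss)
}

# Merge overlapping or book-ended intervals per chromosome (strand ignored).
reduce_intervals <- function(df) {
  if (nrow(df) == 0)
    return(df[, c("chrom", "start", "end")])
  out <- lapply(split(df, df$chrom), function(d) {
    r <- IRanges::reduce(IRanges::IRanges(d$start + 1L, d$end))
    data.frame(
      chrom = rep(d$chrom[1], length(r)),
      start = IRanges::start(r) - 1L,
      end = IRanges::end(r),
      stringsAsFactors = FALSE
    )
  })
  out <- do.call(rbind, out)
  rownames(out) <- NULL
  out[order(out$chrom, out$start), , drop = FALSE]
}
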