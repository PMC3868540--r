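#' Observed base overlap between regions and segments
#'
#' Total number of bases in `regions` that fall inside any `segments`
#' interval; bases overlapped by several segments are counted once.
#'
#' @param regions,segments Interval `data.frame`s.
#' @return Integer base count.
#' @export
observed_overlap <- function(regions, segments) {
  if (nrow(regions) == 0 || nrow(segments) == 0) return(0L)
  r <- reduce_intervals(regions)
  s <- reduce_intervals(segments)
  tot <- 0L
  for (ch in intersect(unique(r$chrom), unique(s$chrom))) {
    ri <- r[r$chrom == ch, ]
    si <- s[s$chrom == ch, ]
    inter <- IRanges::intersect(IRanges::IRanges(ri$start + 1L, ri$end),
                                IRanges::IRanges(si$start + 1L, si$end))
    tot <- tot + sum(IRanges::width(inter))
  }
  as.integer(tot)
}

#' Expected base overlap under a uniform genome model
#'
#' `(total segment bases / genome size) * total region bases`: the overlap
#' expected if regions were placed uniformly at random.
#'
#' @param regions,segments Interval `data.frame`s.
#' @param genome_size Total genome length in bp (> 0).
#' @return Numeric expected base count.
#' @export
expected_overlap <- function(regions, segments, genome_size) {
  if (genome_size <= 0) stop("expected_overlap: genome_size must be > 0")
  seg_bases <- sum(interval_width(reduce_intervals(segments)))
  reg_bases <- sum(interval_width(reduce_intervals(regions)))
  (seg_bases / genome_size) * reg_bases
}

#' Observed/expected fold enrichment of region classes in segment types
#'
#' Cross-tabulates every region class against every segment type (class x
#' specificity present in `segments`) and reports the ratio of observed to
#' expected overlapping bases. Segment types with zero expected bases yield
#' `NA`, never infinity.
#'
#' @param region_classes Named list of interval `data.frame`s (e.g.
#'   `list(gain_NP = ..., loss_NP = ...)`).
#' @param segments Segment `data.frame` with `seg_class` and `specificity`.
#' @param genome_size Total genome length in bp.
#' @return `data.frame`: `region_class`, `seg_type`, `observed`, `expected`,
#'   `fold`.
#' @export
fold_table <- function(region_classes, segments, genome_size) {
  stopifnot(length(region_classes) >= 1, nrow(segments) >= 1)
  seg_type <- paste(segments$seg_class, segments$specificity, sep = ".")
  types <- unique(seg_type)
  rows <- list()
  for (rc in names(region_classes)) {
    for (ty in types) {
      segs <- segments[seg_type == ty, , drop = FALSE]
      obs <- observed_overlap(region_classes[[rc]], segs)
      exp <- expected_overlap(region_classes[[rc]], segs, genome_size)
      rows[[length(rows) + 1]] <- data.frame(
        region_class = rc, seg_type = ty, observed = obs, expected = exp,
        fold = if (exp > 0) obs / exp else NA_real_,
        stringsAsFactors = FALSE
      )
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Fraction of region bases inside segments
#'
#' The summary statistic "what fraction of all change regions falls in this
#' segment type": observed overlap divided by total region bases.
#'
#' @param regions,segments Interval `data.frame`s.
#' @return Fraction in `[0, 1]`.
#' @export
fraction_in_segments <- function(regions, segments) {
  reg_bases <- sum(interval_width(reduce_intervals(regions)))
  if (reg_bases == 0) stop("fraction_in_segments: empty region set")
  observed_overlap(regions, segments) / reg_bases
}
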