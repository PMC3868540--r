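#' Paired ChIP-BisSeq / WG-BisSeq methylation table
#'
#' Pairs methylation between the bound fraction (ChIP-BisSeq) and the total
#' population (WG-BisSeq). In `window200` mode each unit is a window of
#' `width` bp centered on a motif; the window is kept only if EVERY
#' considered cytosine (any CpG cytosine observed in either sample within
#' the window) has coverage of at least `min_cov` in BOTH samples, and its
#' methylation is the coverage-weighted mean per sample. In `cytosine` mode
#' units are individual cytosines passing the joint coverage rule.
#'
#' @param wg_calls,chip_calls Call `data.frame`s from [extract_methylation()].
#' @param hits Motif hit `data.frame`; window centers are [motif_center()]
#'   positions. Callers typically pre-filter to bound hits overlapping LMRs.
#' @param unit `"window200"` or `"cytosine"`.
#' @param min_cov Joint coverage threshold (default 10).
#' @param width Window width for `window200` (default 200).
#' @param weighted Coverage-weighted window means (default) or per-cytosine.
#' @return `data.frame` with locus columns and `wg_pct`, `chip_pct`.
#' @export
paired_table <- function(wg_calls, chip_calls, hits,
                         unit = c("window200", "cytosine"), min_cov = 10,
                         width = 200, weighted = TRUE) {
  unit <- match.arg(unit)
  keyify <- function(d) paste(d$chrom, d$pos, d$strand, sep = "\r")
  if (unit == "cytosine") {
    wg <- wg_calls[wg_calls$n_total >= min_cov, ]
    ch <- chip_calls[chip_calls$n_total >= min_cov, ]
    i <- match(keyify(wg), keyify(ch))
    keep <- !is.na(i)
    out <- data.frame(
      chrom = wg$chrom[keep], pos = wg$pos[keep], strand = wg$strand[keep],
      wg_pct = wg$meth_pct[keep], chip_pct = ch$meth_pct[i[keep]],
      stringsAsFactors = FALSE
    )
    rownames(out) <- NULL
    return(out)
  }
  centers <- motif_center(hits)
  rows <- list()
  skipped_empty <- 0L
  for (j in seq_len(nrow(hits))) {
    ch <- hits$chrom[j]
    lo <- centers[j] - width %/% 2L
    hi <- centers[j] + width %/% 2L
    wg_in <- wg_calls[wg_calls$chrom == ch & wg_calls$pos >= lo &
                        wg_calls$pos < hi, ]
    ch_in <- chip_calls[chip_calls$chrom == ch & chip_calls$pos >= lo &
                          chip_calls$pos < hi, ]
    keys <- union(keyify(wg_in), keyify(ch_in))
    if (!length(keys)) { skipped_empty <- skipped_empty + 1L; next }
    iw <- match(keys, keyify(wg_in))
    ic <- match(keys, keyify(ch_in))
    ok <- !is.na(iw) & !is.na(ic) &
      wg_in$n_total[iw] >= min_cov & ch_in$n_total[ic] >= min_cov
    if (!all(ok)) next  # "all considered cytosines" rule
    wg_pct <- if (weighted) 100 * sum(wg_in$n_meth[iw]) / sum(wg_in$n_total[iw])
              else mean(wg_in$meth_pct[iw])
    chip_pct <- if (weighted) 100 * sum(ch_in$n_meth[ic]) / sum(ch_in$n_total[ic])
                else mean(ch_in$meth_pct[ic])
    rows[[length(rows) + 1]] <- data.frame(
      chrom = ch, start = lo, end = hi, center = centers[j],
      n_cpg = length(keys), wg_pct = wg_pct, chip_pct = chip_pct,
      stringsAsFactors = FALSE
    )
  }
  out <- if (length(rows)) do.call(rbind, rows) else
    data.frame(chrom = character(0), start = integer(0), end = integer(0),
               center = integer(0), n_cpg = integer(0), wg_pct = numeric(0),
               chip_pct = numeric(0))
  rownames(out) <- NULL
  attr(out, "skipped_empty") <- skipped_empty
  out
}

#' Mean deviation and correlation of paired methylation
#'
#' Summarizes the ChIP-minus-WG methylation deviation: its mean, spread and
#' the Pearson correlation of the paired values. Under occupancy-independent
#' ("unlinked") methylation the deviation centers on 0; under deterministic
#' coupling ("static") the bound fraction is unmethylated and the deviation
#' is strongly negative.
#'
#' @param pairs Output of [paired_table()].
#' @return List: `n`, `mean_dev`, `sd_dev`, `median_dev`, `pearson_r`
#'   (`NA` when either column has zero variance).
#' @export
mean_deviation <- function(pairs) {
  if (nrow(pairs) < 2) stop("mean_deviation: need at least 2 pairs")
  dev <- pairs$chip_pct - pairs$wg_pct
  r <- if (stats::sd(pairs$wg_pct) > 0 && stats::sd(pairs$chip_pct) > 0)
    stats::cor(pairs$wg_pct, pairs$chip_pct) else NA_real_
  list(n = nrow(pairs), mean_dev = mean(dev), sd_dev = stats::sd(dev),
       median_dev = stats::median(dev), pearson_r = r)
}

#' Methylation at differentially methylated (allelic) loci
#'
#' At DMRs only one allele is bound and unmethylated, so the population
#' (WG) methylation sits near 50% while ChIP-BisSeq recovers only the bound,
#' unmethylated allele.
#'
#' @param pairs Output of [paired_table()] (window unit).
#' @param dmrs Interval `data.frame` of DMR loci.
#' @return List: `n`, `wg_mean`, `chip_mean`, `wg_median`, `chip_median`;
#'   empty-list result with a warning when no pair overlaps a DMR.
#' @export
dmr_check <- function(pairs, dmrs) {
  loci <- data.frame(chrom = pairs$chrom, start = pairs$start, end = pairs$end)
  ov <- overlap_pairs(loci, dmrs)
  sel <- unique(ov$query)
  if (!length(sel)) {
    warning("no paired loci overlap a DMR")
    return(list(n = 0L))
  }
  list(n = length(sel),
       wg_mean = mean(pairs$wg_pct[sel]), chip_mean = mean(pairs$chip_pct[sel]),
       wg_median = stats::median(pairs$wg_pct[sel]),
       chip_median = stats::median(pairs$chip_pct[sel]))
}

#' Methylation deviation versus distance to the nearest motif
#'
#' For cytosine-unit pairs, computes the distance to the nearest motif
#' center (ties broken to the leftmost center) and the per-cytosine
#' ChIP-minus-WG deviation, plus their Pearson correlation. Used to test
#' whether binding affects proximal cytosines more than distal ones.
#'
#' @param pairs Cytosine-unit output of [paired_table()].
#' @param hits Motif hits to measure distance against (typically bound hits
#'   only).
#' @return `data.frame` with `distance` and `delta`; Pearson r in attribute
#'   `pearson_r`.
#' @export
distance_delta <- function(pairs, hits) {
  if (nrow(hits) == 0) stop("distance_delta: no motif hits supplied")
  centers <- motif_center(hits)
  dist <- rep(NA_real_, nrow(pairs))
  nearest <- rep(NA_integer_, nrow(pairs))
  for (ch in unique(pairs$chrom)) {
    cc <- sort(centers[hits$chrom == ch])
    pi <- which(pairs$chrom == ch)
    if (!length(cc) || !length(pi)) next
    p <- pairs$pos[pi]
    k <- findInterval(p, cc)
    left <- ifelse(k >= 1, cc[pmax(k, 1)], NA_real_)
    right <- ifelse(k < length(cc), cc[pmin(k + 1, length(cc))], NA_real_)
    dl <- abs(p - left)
    dr <- abs(right - p)
    use_left <- !is.na(dl) & (is.na(dr) | dl <= dr)  # tie -> leftmost center
    dist[pi] <- ifelse(use_left, dl, dr)
    nearest[pi] <- as.integer(ifelse(use_left, left, right))
  }
  out <- data.frame(chrom = pairs$chrom, pos = pairs$pos,
                    distance = dist, nearest_center = nearest,
                    delta = pairs$chip_pct - pairs$wg_pct,
                    stringsAsFactors = FALSE)
  ok <- is.finite(out$distance)
  r <- if (sum(ok) >= 3 && stats::sd(out$distance[ok]) > 0 &&
           stats::sd(out$delta[ok]) > 0)
    stats::cor(out$distance[ok], out$delta[ok]) else NA_real_
  attr(out, "pearson_r") <- r
  out
}

#' Centered running mean
#'
#' Sliding mean over `k` consecutive points, truncated at the edges (the
#' window shrinks near the boundaries rather than dropping points).
#'
#' @param x Numeric vector.
#' @param k Odd window size.
#' @return Numeric vector of the same length.
#' @export
running_mean <- function(x, k) {
  n <- length(x)
  h <- (k - 1) %/% 2
  vapply(seq_len(n), function(i) mean(x[max(1, i - h):min(n, i + h)]), 0)
}

#' Motif-CpG methylation versus binding strength
#'
#' Sorts motif-CpG methylation observations by ChIP enrichment and overlays
#' a centered running mean, the scatter-plus-trend view that separates
#' strongly bound/unmethylated, weakly bound/intermediate and unbound sites.
#'
#' @param points `data.frame` with `enrichment` and `meth_pct` columns (one
#'   row per motif CpG passing the coverage filter).
#' @param k Running-mean window in points (default 101; shrunk with a
#'   warning if fewer points are available).
#' @return `points` sorted by enrichment with a `run_mean` column; the
#'   window actually used is in attribute `k`.
#' @export
motif_cpg_curve <- function(points, k = 101) {
  stopifnot(all(c("enrichment", "meth_pct") %in% names(points)))
  n <- nrow(points)
  if (n < k) {
    k <- max(1L, n - (1L - n %% 2L))  # largest odd <= n
    warning("fewer points than running-mean window; k shrunk to ", k)
  }
  out <- points[order(points$enrichment), , drop = FALSE]
  out$run_mean <- running_mean(out$meth_pct, k)
  rownames(out) <- NULL
  attr(out, "k") <- k
  out
}

#' Correlation between per-segment changes in two marks
#'
#' Pearson correlation between aligned per-segment change vectors, e.g.
#' the log2 fold change in 5hmC and the change in methylation percentage
#' across LMRs between two cell states.
#'
#' @param a,b Numeric vectors aligned by segment.
#' @return Pearson r.
#' @export
change_correlation <- function(a, b) {
  if (length(a) != length(b))
    stop("change_correlation: vectors must be aligned (equal length)")
  stats::cor(a, b, use = "complete.obs")
}
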