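#' Shift alignments and weight by inverse hit count
#'
#' Each alignment is reduced to a single tag point: plus-strand reads at
#' `start + shift`, minus-strand reads at `end - 1 - shift` (mirror rule),
#' approximating the fragment midpoint when `shift` is half the fragment
#' length. Each placement carries weight `1 / n_hits`, so the placements of
#' one multi-mapping read sum to exactly 1. Tags shifted off the chromosome
#' are clamped to the boundary and counted in the `clamped` attribute.
#'
#' @param aln Alignment `data.frame`.
#' @param shift Shift in bp (default 60, half of a 120 bp fragment).
#' @param sizes Optional named chromosome sizes used for clamping.
#' @return `data.frame`: `chrom`, `pos`, `weight`, `read_id`.
#' @export
shift_and_weight <- function(aln, shift = 60, sizes = NULL) {
  stopifnot(shift >= 0)
  pos <- ifelse(aln$strand == "-", aln$end - 1L - shift, aln$start + shift)
  clamped <- sum(pos < 0)
  pos <- pmax(pos, 0L)
  if (!is.null(sizes)) {
    lim <- sizes[aln$chrom] - 1L
    clamped <- clamped + sum(pos > lim)
    pos <- pmin(pos, lim)
  }
  out <- data.frame(chrom = aln$chrom, pos = as.integer(pos),
                    weight = 1 / aln$n_hits, read_id = aln$read_id,
                    stringsAsFactors = FALSE)
  attr(out, "clamped") <- clamped
  out
}

#' Weighted tag counts per window
#'
#' Each tag contributes its weight to every window containing its point;
#' windows may overlap (sliding tilings).
#'
#' @param tags Tag `data.frame` from [shift_and_weight()].
#' @param windows Interval `data.frame`.
#' @return Numeric vector of weighted counts, one per window row.
#' @export
count_windows <- function(tags, windows) {
  out <- numeric(nrow(windows))
  if (nrow(tags) == 0 || nrow(windows) == 0) return(out)
  pts <- data.frame(chrom = tags$chrom, start = tags$pos, end = tags$pos + 1L)
  ov <- overlap_pairs(pts, windows)
  if (nrow(ov) == 0) return(out)
  sums <- rowsum(tags$weight[ov$query], ov$subject)
  out[as.integer(rownames(sums))] <- sums[, 1]
  out
}

#' Library size of a weighted tag set
#'
#' Total number of aligned reads: the sum of placement weights, which equals
#' the number of distinct reads because each read's placements sum to 1.
#'
#' @param tags Tag `data.frame`.
#' @return Numeric scalar.
#' @export
library_size <- function(tags) sum(tags$weight)

#' IP enrichment over control in fixed intervals
#'
#' Weighted counts in each interval are scaled to the smaller library and
#' regularized with a pseudocount before the log-ratio, the same functional
#' form as the differential-window fold change ([log2fc()]). This
#' normalization is a reconstruction (the exact upstream formula is not
#' restated in the source methods) and is fully parameterized.
#'
#' @param ip_tags,control_tags Tag `data.frame`s.
#' @param intervals Interval `data.frame` (e.g. 200 bp windows at motifs).
#' @param pseudo Pseudocount on the scaled counts (default 8).
#' @return `intervals` with `ip_count`, `control_count`, `log2_enrichment`.
#' @export
enrichment <- function(ip_tags, control_tags, intervals, pseudo = 8) {
  validate_intervals(intervals)
  if (nrow(intervals) == 0) stop("enrichment: empty interval set")
  n_ip <- count_windows(ip_tags, intervals)
  n_ct <- count_windows(control_tags, intervals)
  N_ip <- library_size(ip_tags)
  N_ct <- library_size(control_tags)
  out <- intervals
  out$ip_count <- n_ip
  out$control_count <- n_ct
  out$log2_enrichment <- log2fc(n_es = n_ct, n_np = n_ip,
                                N_es = N_ct, N_np = N_ip, p = pseudo)
  out
}

#' Classify motif sites by enrichment
#'
#' Two ordered thresholds partition sites into `unbound` (score below the
#' lower), `weak` (between) and `strong` (above the upper) classes.
#'
#' @param scores Numeric log2 enrichment per site.
#' @param thresholds Length-2 increasing numeric vector (default `c(1, 3)`).
#' @return Ordered factor with levels `unbound < weak < strong`.
#' @export
classify_sites <- function(scores, thresholds = c(1, 3)) {
  if (length(thresholds) != 2 || thresholds[1] >= thresholds[2])
    stop("classify_sites: thresholds must be two increasing values")
  cut(scores, breaks = c(-Inf, thresholds, Inf),
      labels = c("unbound", "weak", "strong"), ordered_result = TRUE)
}

#' Average signal profile around anchors
#'
#' Bins the flanking region `[anchor - flank, anchor + flank)` and averages
#' across anchors. For tags the per-bin signal is the weighted count scaled
#' per million aligned reads; for methylation calls it is the mean
#' percentage. Anchors whose flank extends beyond the chromosome are dropped
#' (counted in attribute `dropped`).
#'
#' @param x Tag or call `data.frame`.
#' @param anchors `data.frame` with `chrom` and `center`.
#' @param flank Half-width in bp (default 3000).
#' @param bin Bin width in bp (default 50).
#' @param value `"tags"` or `"methylation"`.
#' @param sizes Named chromosome sizes (required for edge dropping).
#' @return List with `profile` (mean per bin), `offsets` (bin centers
#'   relative to the anchor) and `matrix` (anchors x bins).
#' @export
average_profile <- function(x, anchors, flank = 3000, bin = 50,
                            value = c("tags", "methylation"), sizes = NULL) {
  value <- match.arg(value)
  stopifnot(flank %% bin == 0)
  if (!is.null(sizes)) {
    ok <- anchors$center - flank >= 0 &
      anchors$center + flank <= sizes[anchors$chrom]
    dropped <- sum(!ok)
    anchors <- anchors[ok, , drop = FALSE]
  } else dropped <- 0L
  nb <- 2L * flank %/% bin
  edges <- seq(-flank, flank, by = bin)
  mat <- matrix(NA_real_, nrow(anchors), nb)
  pos <- if (value == "tags") x$pos else x$pos
  scale <- if (value == "tags") 1e6 / library_size(x) else 1
  for (i in seq_len(nrow(anchors))) {
    sel <- x$chrom == anchors$chrom[i] &
      pos >= anchors$center[i] - flank & pos < anchors$center[i] + flank
    rel <- pos[sel] - anchors$center[i]
    b <- findInterval(rel, edges, rightmost.closed = FALSE)
    if (value == "tags") {
      w <- rowsum(x$weight[sel], b)
      row <- numeric(nb)
      row[as.integer(rownames(w))] <- w[, 1] * scale
      mat[i, ] <- row
    } else {
      row <- rep(NA_real_, nb)
      if (any(sel)) {
        m <- tapply(x$meth_pct[sel], b, mean)
        row[as.integer(names(m))] <- m
      }
      mat[i, ] <- row
    }
  }
  prof <- colMeans(mat, na.rm = TRUE)
  out <- list(profile = prof, offsets = edges[-length(edges)] + bin / 2,
              matrix = mat)
  attr(out, "dropped") <- dropped
  out
}
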