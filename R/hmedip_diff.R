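#' Differential-window parameters
#'
#' The defaults are the published procedure: 1 kb windows overlapping by
#' 500 bp, pseudocount 8 on min-library-scaled counts, and a dual-replicate
#' cutoff of |log2FC| > 3.
#'
#' @param p Pseudocount (> 0).
#' @param win Window size, bp.
#' @param step Step between window starts, bp (`step <= win`).
#' @param threshold |log2FC| cutoff (> 0, strict inequality).
#' @return List of class `fc_params`.
#' @export
fc_params <- function(p = 8, win = 1000, step = 500, threshold = 3) {
  if (p <= 0) stop("fc_params: p must be > 0")
  if (step > win) stop("fc_params: step must be <= win")
  if (threshold <= 0) stop("fc_params: threshold must be > 0")
  structure(list(p = p, win = as.integer(win), step = as.integer(step),
                 threshold = threshold), class = "fc_params")
}

#' Pseudocounted log2 fold change between two libraries
#'
#' `log2((n_np/N_np * m + p) / (n_es/N_es * m + p))` with
#' `m = min(N_es, N_np)`: per-window weighted counts are scaled to the
#' smaller library and regularized with the pseudocount `p` so that
#' low-count windows are not dominated by sampling noise. Antisymmetric
#' under swapping the two conditions; shrinks toward 0 as `p` grows.
#'
#' @param n_es,n_np Weighted counts in the window for each condition.
#' @param N_es,N_np Total aligned reads in each library (> 0).
#' @param p Pseudocount (default 8).
#' @return Numeric log2 fold change (NP over ES), vectorized over windows.
#' @export
log2fc <- function(n_es, n_np, N_es, N_np, p = 8) {
  if (!all(is.finite(c(n_es, n_np, N_es, N_np, p))))
    stop("log2fc: non-finite input")
  if (any(N_es <= 0) || any(N_np <= 0))
    stop("log2fc: library sizes must be > 0")
  if (any(p <= 0)) stop("log2fc: p must be > 0")
  m <- pmin(N_es, N_np)
  log2((n_np / N_np * m + p) / (n_es / N_es * m + p))
}

#' Tile a genome with sliding windows
#'
#' Windows start at 0 on each chromosome and advance by `step`. Full `win`-
#' sized windows are emitted while they fit; one trailing partial window
#' `[s, len)` is added only when it is at least `step` long and extends
#' beyond the coverage of the last full window.
#'
#' @param sizes Named integer chromosome sizes.
#' @param win Window size, bp.
#' @param step Step, bp.
#' @return Interval `data.frame`.
#' @export
tile_genome <- function(sizes, win = 1000, step = 500) {
  out <- lapply(names(sizes), function(ch) {
    len <- as.integer(sizes[[ch]])
    nfull <- if (len >= win) (len - win) %/% step + 1L else 0L
    starts <- if (nfull > 0) seq(0L, by = step, length.out = nfull) else integer(0)
    ends <- starts + win
    covered <- if (nfull > 0) ends[nfull] else 0L
    s2 <- nfull * step
    if (len - s2 >= step && len > covered) {
      starts <- c(starts, s2)
      ends <- c(ends, len)
    }
    if (!length(starts)) return(NULL)
    data.frame(chrom = ch, start = starts, end = ends, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, out)
  if (is.null(out))
    out <- data.frame(chrom = character(0), start = integer(0), end = integer(0))
  rownames(out) <- NULL
  out
}

#' Sliding-window fold changes between two conditions
#'
#' Tiles the genome, counts weighted tags per window in each condition and
#' applies [log2fc()]. Library sizes are the summed tag weights (one unit
#' per distinct read).
#'
#' @param tags_es,tags_np Tag `data.frame`s from [shift_and_weight()].
#' @param sizes Named chromosome sizes.
#' @param params [fc_params()] list.
#' @return Window `data.frame` with `n_ES`, `n_NP`, `log2fc`; library sizes
#'   in attributes `N_ES`, `N_NP`.
#' @export
window_scan <- function(tags_es, tags_np, sizes, params = fc_params()) {
  wins <- tile_genome(sizes, params$win, params$step)
  wins$n_ES <- count_windows(tags_es, wins)
  wins$n_NP <- count_windows(tags_np, wins)
  N_es <- library_size(tags_es)
  N_np <- library_size(tags_np)
  wins$log2fc <- log2fc(wins$n_ES, wins$n_NP, N_es, N_np, params$p)
  attr(wins, "N_ES") <- N_es
  attr(wins, "N_NP") <- N_np
  attr(wins, "params") <- params
  wins
}

#' Flag windows consistent across two replicates
#'
#' A window is a `gain` when log2FC exceeds the threshold in BOTH replicates
#' and a `loss` when it is below the negated threshold in both (strict
#' inequalities: a window at exactly the threshold is unflagged, as are
#' discordant signs).
#'
#' @param rep1,rep2 Window `data.frame`s from [window_scan()] over the
#'   identical tiling.
#' @param threshold |log2FC| cutoff (default 3).
#' @return The tiling with `log2fc_rep1`, `log2fc_rep2` and `flag`
#'   (`"gain"`, `"loss"` or `"none"`).
#' @export
consistent_windows <- function(rep1, rep2, threshold = 3) {
  if (!identical(rep1[c("chrom", "start", "end")],
                 rep2[c("chrom", "start", "end")]))
    stop("consistent_windows: replicate tilings differ")
  out <- rep1[c("chrom", "start", "end")]
  out$log2fc_rep1 <- rep1$log2fc
  out$log2fc_rep2 <- rep2$log2fc
  out$flag <- ifelse(rep1$log2fc > threshold & rep2$log2fc > threshold, "gain",
              ifelse(rep1$log2fc < -threshold & rep2$log2fc < -threshold,
                     "loss", "none"))
  out
}

#' Merge flagged windows into regions
#'
#' Overlapping or book-ended windows of the same class are merged into
#' maximal intervals; the two classes are merged independently (a window
#' cannot satisfy both strict inequalities, so classes never share a
#' window).
#'
#' @param flagged Output of [consistent_windows()].
#' @return List with interval `data.frame`s `gain` and `loss`.
#' @export
merge_regions <- function(flagged) {
  lapply(stats::setNames(c("gain", "loss"), c("gain", "loss")), function(cl) {
    reduce_intervals(flagged[flagged$flag == cl, , drop = FALSE])
  })
}
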