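#' CpG dinucleotide coordinates of a genome
#'
#' @param genome Named character vector of sequences.
#' @return `data.frame` with `chrom` and `pos` (0-based position of the
#'   plus-strand C of each CG).
#' @export
cpg_table <- function(genome) {
  out <- lapply(names(genome), function(ch) {
    m <- gregexpr("CG", toupper(genome[[ch]]), fixed = TRUE)[[1]]
    if (m[1] == -1) return(NULL)
    data.frame(chrom = ch, pos = as.integer(m) - 1L, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, out)
  if (is.null(out))
    out <- data.frame(chrom = character(0), pos = integer(0))
  out
}

#' Per-cytosine methylation calls from bisulfite alignments
#'
#' Reads must be ungapped and carry reference-projected sequences (`seq`
#' column, as produced by the simulator or parsed from SAM). For a
#' plus-strand CpG cytosine covered by a plus-strand read, a read base `C`
#' counts as methylated and `T` as unmethylated; the symmetric rule on the
#' minus strand reads `G` (methylated) or `A` (unmethylated) at the guanine
#' position of the CpG. Any other base increments a mismatch counter
#' (attribute `mismatches`) and is not counted. Bisulfite cannot distinguish
#' 5mC from 5hmC, so both register as methylated.
#'
#' Plus- and minus-strand cytosines of one CpG are reported as separate
#' calls; use [collapse_strands()] to pool the pair.
#'
#' @param aln Alignment `data.frame` with `seq` column.
#' @param genome Named character vector of sequences.
#' @param cpg Optional CpG table (defaults to `cpg_table(genome)`).
#' @return `data.frame`: `chrom`, `pos` (0-based position of the cytosine
#'   itself), `strand`, `n_meth`, `n_total`, `meth_pct`, sorted by position.
#' @export
extract_methylation <- function(aln, genome, cpg = NULL) {
  if (is.null(cpg)) cpg <- cpg_table(genome)
  if (nrow(cpg) == 0 || nrow(aln) == 0)
    return(data.frame(chrom = character(0), pos = integer(0),
                      strand = character(0), n_meth = integer(0),
                      n_total = integer(0), meth_pct = numeric(0)))
  if (!"seq" %in% names(aln))
    stop("extract_methylation: alignments must carry read sequences")
  sizes <- seq_sizes(genome)
  if (any(aln$end > sizes[aln$chrom] | aln$start < 0))
    stop("extract_methylation: read span outside genome")
  cpg_by_chrom <- split(cpg$pos, cpg$chrom)
  cpg_by_chrom <- lapply(cpg_by_chrom, sort)

  poss <- vector("list", nrow(aln))
  stds <- vector("list", nrow(aln))
  meth <- vector("list", nrow(aln))
  mism <- 0L
  for (i in seq_len(nrow(aln))) {
    P <- cpg_by_chrom[[aln$chrom[i]]]
    if (is.null(P)) next
    start <- aln$start[i]; end <- aln$end[i]
    if (aln$strand[i] == "+") {
      lo <- findInterval(start - 0.5, P) + 1L
      hi <- findInterval(end - 0.5, P)
      if (hi < lo) next
      cp <- P[lo:hi]
      base <- substring(aln$seq[i], cp - start + 1L, cp - start + 1L)
      ok <- base %in% c("C", "T")
      mism <- mism + sum(!ok)
      if (!any(ok)) next
      poss[[i]] <- cp[ok]
      stds[[i]] <- rep("+", sum(ok))
      meth[[i]] <- base[ok] == "C"
    } else {
      Q <- P + 1L  # guanine position = minus-strand cytosine
      lo <- findInterval(start - 0.5, Q) + 1L
      hi <- findInterval(end - 0.5, Q)
      if (hi < lo) next
      cq <- Q[lo:hi]
      base <- substring(aln$seq[i], cq - start + 1L, cq - start + 1L)
      ok <- base %in% c("G", "A")
      mism <- mism + sum(!ok)
      if (!any(ok)) next
      poss[[i]] <- cq[ok]
      stds[[i]] <- rep("-", sum(ok))
      meth[[i]] <- base[ok] == "G"
    }
    # reuse chrom later via rep()
  }
  nper <- lengths(poss)
  if (sum(nper) == 0) {
    out <- data.frame(chrom = character(0), pos = integer(0),
                      strand = character(0), n_meth = integer(0),
                      n_total = integer(0), meth_pct = numeric(0))
    attr(out, "mismatches") <- mism
    return(out)
  }
  obs <- data.frame(
    chrom = rep(aln$chrom, nper),
    pos = unlist(poss),
    strand = unlist(stds),
    m = unlist(meth),
    stringsAsFactors = FALSE
  )
  key <- paste(obs$chrom, obs$pos, obs$strand, sep = "\r")
  agg <- rowsum(cbind(n_meth = as.integer(obs$m), n_total = 1L), key)
  parts <- strsplit(rownames(agg), "\r", fixed = TRUE)
  calls <- data.frame(
    chrom = vapply(parts, `[`, "", 1),
    pos = as.integer(vapply(parts, `[`, "", 2)),
    strand = vapply(parts, `[`, "", 3),
    n_meth = as.integer(agg[, "n_meth"]),
    n_total = as.integer(agg[, "n_total"]),
    stringsAsFactors = FALSE
  )
  calls$meth_pct <- 100 * calls$n_meth / calls$n_total
  calls <- calls[order(calls$chrom, calls$pos, calls$strand), ]
  rownames(calls) <- NULL
  attr(calls, "mismatches") <- mism
  calls
}

#' Pool the two strands of each CpG
#'
#' Sums counts of the plus-strand cytosine and the paired minus-strand
#' cytosine (at `pos + 1`) into a single strandless call at the CpG's C
#' position.
#'
#' @param calls Call `data.frame` from [extract_methylation()].
#' @return Collapsed call `data.frame` (strand `"."`).
#' @export
collapse_strands <- function(calls) {
  cpg_pos <- ifelse(calls$strand == "-", calls$pos - 1L, calls$pos)
  key <- paste(calls$chrom, cpg_pos, sep = "\r")
  agg <- rowsum(cbind(calls$n_meth, calls$n_total), key)
  parts <- strsplit(rownames(agg), "\r", fixed = TRUE)
  out <- data.frame(
    chrom = vapply(parts, `[`, "", 1),
    pos = as.integer(vapply(parts, `[`, "", 2)),
    strand = ".",
    n_meth = as.integer(agg[, 1]),
    n_total = as.integer(agg[, 2]),
    stringsAsFactors = FALSE
  )
  out$meth_pct <- 100 * out$n_meth / out$n_total
  out <- out[order(out$chrom, out$pos), ]
  rownames(out) <- NULL
  out
}

#' Coverage-filter methylation calls
#'
#' Keeps calls with `n_total >= min_cov`. In joint mode (`joint_with` given)
#' a position is kept only if it passes the threshold in BOTH samples.
#'
#' @param calls Call `data.frame`.
#' @param min_cov Minimum coverage (default 10).
#' @param joint_with Optional second call set for the joint rule.
#' @return Filtered calls.
#' @export
filter_coverage <- function(calls, min_cov = 10, joint_with = NULL) {
  keep <- calls$n_total >= min_cov
  if (!is.null(joint_with)) {
    other <- joint_with[joint_with$n_total >= min_cov, ]
    ok_keys <- paste(other$chrom, other$pos, other$strand, sep = "\r")
    keep <- keep & paste(calls$chrom, calls$pos, calls$strand, sep = "\r") %in% ok_keys
  }
  out <- calls[keep, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Average methylation in fixed-width windows
#'
#' For each center, averages calls in `[center - width/2, center + width/2)`.
#' The default is the coverage-weighted mean `100 * sum(n_meth) / sum(n_total)`;
#' `weighted = FALSE` gives the unweighted per-cytosine mean. Windows with no
#' passing call return `NA`.
#'
#' @param calls Call `data.frame` (already coverage-filtered if desired).
#' @param centers `data.frame` with `chrom` and `center` columns, or an
#'   integer vector (then `chrom` must name a single chromosome).
#' @param width Window width in bp (default 200).
#' @param weighted Coverage-weighted (default) or per-cytosine mean.
#' @param chrom Chromosome name when `centers` is a bare vector.
#' @return Numeric vector of window methylation percentages.
#' @export
window_methylation <- function(calls, centers, width = 200, weighted = TRUE,
                               chrom = NULL) {
  if (!is.data.frame(centers))
    centers <- data.frame(chrom = chrom, center = as.integer(centers))
  win <- data.frame(chrom = centers$chrom,
                    start = centers$center - width %/% 2L,
                    end = centers$center + width %/% 2L)
  pts <- data.frame(chrom = calls$chrom, start = calls$pos,
                    end = calls$pos + 1L)
  ov <- overlap_pairs(pts, win)
  out <- rep(NA_real_, nrow(win))
  if (nrow(ov) == 0) return(out)
  for (w in unique(ov$subject)) {
    idx <- ov$query[ov$subject == w]
    out[w] <- if (weighted) {
      100 * sum(calls$n_meth[idx]) / sum(calls$n_total[idx])
    } else {
      mean(calls$meth_pct[idx])
    }
  }
  out
}
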