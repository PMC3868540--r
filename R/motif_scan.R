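#' Construct a position weight matrix
#'
#' Rows (motif positions) are regularized with an additive pseudocount and
#' renormalized, so every entry is strictly positive and log-odds scores are
#' finite except at `N` bases.
#'
#' @param mat Numeric matrix, one row per position, columns A, C, G, T
#'   (probabilities or counts).
#' @param background Background base probabilities (A, C, G, T).
#' @param pseudocount Additive regularizer applied per cell before
#'   renormalization.
#' @return A `pwm` object: list with `matrix`, `background`, `length`.
#' @export
pwm <- function(mat, background = rep(0.25, 4), pseudocount = 0.01) {
  mat <- as.matrix(mat)
  stopifnot(ncol(mat) == 4, all(mat >= 0), length(background) == 4)
  colnames(mat) <- c("A", "C", "G", "T")
  mat <- mat / rowSums(mat)
  mat <- mat + pseudocount
  mat <- mat / rowSums(mat)
  background <- background / sum(background)
  if (any(abs(rowSums(mat) - 1) > 1e-9))
    stop("pwm error: rows do not sum to 1 after regularization")
  if (any(mat <= 0))
    stop("pwm error: non-positive entries after regularization")
  structure(list(matrix = mat, background = background, length = nrow(mat)),
            class = "pwm")
}

#' @export
print.pwm <- function(x, ...) {
  cat("Position weight matrix,", x$length, "positions; consensus:",
      pwm_consensus(x), "\n")
  invisible(x)
}

#' Consensus sequence of a PWM
#'
#' @param p A `pwm` object.
#' @return Character string of per-position argmax letters.
#' @export
pwm_consensus <- function(p) {
  paste(colnames(p$matrix)[apply(p$matrix, 1, which.max)], collapse = "")
}

#' Write a PWM as tab text
#'
#' @param p A `pwm` object.
#' @param path Output file.
#' @return `path`, invisibly.
#' @export
write_pwm <- function(p, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines("# PWM columns: A C G T", con)
  utils::write.table(format(p$matrix, digits = 6), con, sep = "\t",
                     quote = FALSE, row.names = FALSE, col.names = FALSE)
  invisible(path)
}

BASES <- c("A", "C", "G", "T")

revcomp <- function(s) {
  chartr("ACGTacgt", "TGCAtgca",
         vapply(s, function(x) paste(rev(strsplit(x, "")[[1]]), collapse = ""), ""))
}

#' Log-odds score of a single window
#'
#' `sum_i log2(p_i(base_i) / bg(base_i))` in bits; any non-ACGT base makes
#' the score `-Inf`.
#'
#' @param p A `pwm` object.
#' @param sequence Character string of length `p$length`.
#' @return Score in bits.
#' @export
score_window <- function(p, sequence) {
  chars <- strsplit(toupper(sequence), "")[[1]]
  if (length(chars) != p$length)
    stop("score_window: sequence length ", length(chars),
         " != pwm length ", p$length)
  idx <- match(chars, BASES)
  if (anyNA(idx)) return(-Inf)
  sum(log2(p$matrix[cbind(seq_len(p$length), idx)] / p$background[idx]))
}

# Vector of window scores over a base-index vector for (a slice of) a pwm.
# rows: which pwm rows to use. Returns scores for starts 1..(n - k + 1).
slide_scores <- function(p, idx, rows = seq_len(p$length)) {
  k <- length(rows)
  n <- length(idx)
  if (n < k) return(numeric(0))
  lg <- log2(sweep(p$matrix, 2, p$background, "/"))
  s <- numeric(n - k + 1)
  for (j in seq_len(k)) {
    col <- idx[j:(n - k + j)]
    v <- lg[rows[j], col]
    v[is.na(col)] <- -Inf
    s <- s + v
  }
  s
}

#' Scan a genome with a PWM
#'
#' Both strands are scanned with log2-odds scores. In gapped mode
#' (`linker_after` set) a variable-length unscored linker is allowed after
#' that motif position: the score at a start is the maximum over linker
#' lengths in `linker_range`, ties resolved to the smallest linker. Hits on
#' the same strand that overlap are resolved greedily by descending score
#' (optional). Hit intervals are reported in reference (plus-strand)
#' coordinates; their width is `pwm length + linker_len`.
#'
#' @param p A `pwm` object.
#' @param genome Named character vector of sequences.
#' @param threshold Minimum score in bits.
#' @param linker_range Integer vector of allowed linker lengths (e.g. `0:11`),
#'   or `NULL` for ungapped scanning.
#' @param linker_after Motif position (1-based) after which the linker is
#'   inserted; required when `linker_range` is given.
#' @param motif_id Identifier stored with each hit.
#' @param resolve_overlaps Drop same-strand overlapping hits, keeping the
#'   best-scoring one (greedy).
#' @return `data.frame`: `chrom`, `start`, `end`, `strand`, `score`,
#'   `linker_len`, `motif_id`, sorted by position.
#' @export
scan_pwm <- function(p, genome, threshold, linker_range = NULL,
                     linker_after = NULL, motif_id = "motif",
                     resolve_overlaps = TRUE) {
  gapped <- !is.null(linker_range)
  if (gapped) {
    stopifnot(!is.null(linker_after), linker_after >= 1,
              linker_after < p$length, all(linker_range >= 0))
    linker_range <- sort(unique(as.integer(linker_range)))
  }
  res <- list()
  for (ch in names(genome)) {
    n <- nchar(genome[[ch]])
    for (std in c("+", "-")) {
      s <- if (std == "+") genome[[ch]] else revcomp(genome[[ch]])
      idx <- match(strsplit(toupper(s), "")[[1]], BASES)
      if (!gapped) {
        sc <- slide_scores(p, idx)
        keep <- which(sc >= threshold)
        if (!length(keep)) next
        w <- p$length
        st <- keep - 1L   # 0-based on scanned strand
        hit <- data.frame(scan_start = st, score = sc[keep], linker_len = 0L,
                          width = w)
      } else {
        left <- slide_scores(p, idx, rows = seq_len(linker_after))
        right <- slide_scores(p, idx, rows = (linker_after + 1):p$length)
        rlen <- p$length - linker_after
        best <- rep(-Inf, length(left))
        bestl <- rep(NA_integer_, length(left))
        for (l in linker_range) {
          # right part starts at window position linker_after + l (0-based)
          off <- linker_after + l
          nn <- length(idx) - (p$length + l) + 1
          if (nn < 1) next
          tot <- left[seq_len(nn)] + right[seq_len(nn) + off]
          upd <- which(tot > best[seq_len(nn)])  # strict: smallest linker wins ties
          best[upd] <- tot[upd]
          bestl[upd] <- l
        }
        keep <- which(best >= threshold & !is.na(bestl))
        if (!length(keep)) next
        hit <- data.frame(scan_start = keep - 1L, score = best[keep],
                          linker_len = bestl[keep],
                          width = p$length + bestl[keep])
      }
      start0 <- if (std == "+") hit$scan_start else n - hit$scan_start - hit$width
      res[[length(res) + 1]] <- data.frame(
        chrom = ch, start = start0, end = start0 + hit$width, strand = std,
        score = hit$score, linker_len = hit$linker_len, motif_id = motif_id,
        stringsAsFactors = FALSE
      )
    }
  }
  if (!length(res)) {
    warning("no hits at threshold ", threshold)
    return(data.frame(chrom = character(0), start = integer(0), end = integer(0),
                      strand = character(0), score = numeric(0),
                      linker_len = integer(0), motif_id = character(0)))
  }
  hits <- do.call(rbind, res)
  if (resolve_overlaps) {
    keep <- logical(nrow(hits))
    for (grp in split(seq_len(nrow(hits)),
                      paste(hits$chrom, hits$strand))) {
      ord <- grp[order(-hits$score[grp], hits$start[grp])]
      taken_s <- integer(0)
      taken_e <- integer(0)
      for (i in ord) {
        if (!any(hits$start[i] < taken_e & hits$end[i] > taken_s)) {
          keep[i] <- TRUE
          taken_s <- c(taken_s, hits$start[i])
          taken_e <- c(taken_e, hits$end[i])
        }
      }
    }
    hits <- hits[keep, , drop = FALSE]
  }
  hits <- hits[order(hits$chrom, hits$start, hits$strand), , drop = FALSE]
  rownames(hits) <- NULL
  hits
}

#' Annotate CpG positions within motif hits
#'
#' Records the 0-based offsets, relative to the hit interval start, of the
#' plus-strand C of every CG dinucleotide fully inside the match span
#' (reference orientation, independent of hit strand).
#'
#' @param hits Hit `data.frame` from [scan_pwm()].
#' @param genome Named character vector of sequences.
#' @return `hits` with a list column `cpg_offsets` added.
#' @export
annotate_cpg <- function(hits, genome) {
  hits$cpg_offsets <- lapply(seq_len(nrow(hits)), function(i) {
    s <- substr(genome[[hits$chrom[i]]], hits$start[i] + 1, hits$end[i])
    m <- gregexpr("CG", s, fixed = TRUE)[[1]]
    if (m[1] == -1) integer(0) else as.integer(m) - 1L
  })
  hits
}

#' Does a hit carry a CpG at given motif offsets?
#'
#' Position filter used to restrict analyses to CpGs at a fixed place in the
#' motif (offsets are 0-based relative to the hit start; offset 4 means the
#' CG whose C sits at motif position 5 in 1-based coordinates).
#'
#' @param hits Annotated hits (see [annotate_cpg()]).
#' @param offsets Integer offsets to test.
#' @return Logical vector, `TRUE` where any CpG offset is in `offsets`.
#' @export
cpg_at_offsets <- function(hits, offsets) {
  vapply(hits$cpg_offsets, function(o) any(o %in% offsets), TRUE)
}

#' Motif center positions
#'
#' Center convention: `start + floor(width / 2)`.
#'
#' @param hits Hit `data.frame`.
#' @return Integer vector of center coordinates (0-based).
#' @export
motif_center <- function(hits) {
  as.integer(hits$start + (hits$end - hits$start) %/% 2)
}
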