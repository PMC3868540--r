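#' Read a FASTA genome
#'
#' Sequences are upper-cased and named by the header token before the first
#' whitespace.
#'
#' @param path FASTA file.
#' @return Named character vector, one element per record.
#' @export
read_fasta <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  if (file.size(path) == 0) {
    warning("empty FASTA file: ", path)
    return(stats::setNames(character(0), character(0)))
  }
  set <- tryCatch(
    Biostrings::readDNAStringSet(path),
    error = function(e) stop("malformed FASTA (", path, "): ", conditionMessage(e))
  )
  seqs <- toupper(as.character(set))
  names(seqs) <- vapply(strsplit(names(set), "\\s+"), `[`, "", 1)
  seqs
}

#' Write sequences as FASTA
#'
#' @param seqs Named character vector of sequences.
#' @param path Output file.
#' @return `path`, invisibly.
#' @export
write_fasta <- function(seqs, path) {
  Biostrings::writeXStringSet(Biostrings::DNAStringSet(seqs), path)
  invisible(path)
}

seq_sizes <- function(seqs) vapply(seqs, nchar, 0L)

SEG_CLASSES <- c("FMR", "UMR", "LMR")
SEG_SPECIFICITIES <- c("constitutive", "ES_specific", "NP_specific", "NA")

#' Read methylome segment annotations
#'
#' Expects BED6+2: the six standard BED columns followed by the segment class
#' (`FMR`, `UMR` or `LMR`) and its cell-type specificity (`constitutive`,
#' `ES_specific`, `NP_specific` or `NA`). `track`/`browser`/`#` header lines
#' are skipped. Segments of the same class must not overlap.
#'
#' @param path BED6+2 file.
#' @return `data.frame` with columns `chrom`, `start`, `end`, `name`,
#'   `score`, `strand`, `seg_class`, `specificity`.
#' @export
read_segments <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  lines <- lines[!grepl("^(track|browser|#)", lines)]
  if (length(lines) == 0)
    return(data.frame(chrom = character(0), start = integer(0), end = integer(0),
                      name = character(0), score = numeric(0), strand = character(0),
                      seg_class = character(0), specificity = character(0)))
  f <- strsplit(lines, "\t")
  if (any(lengths(f) < 8))
    stop("segment BED format error: expected 8 columns (BED6 + class + specificity)")
  df <- data.frame(
    chrom = vapply(f, `[`, "", 1),
    start = as.integer(vapply(f, `[`, "", 2)),
    end = as.integer(vapply(f, `[`, "", 3)),
    name = vapply(f, `[`, "", 4),
    score = as.numeric(vapply(f, `[`, "", 5)),
    strand = vapply(f, `[`, "", 6),
    seg_class = vapply(f, `[`, "", 7),
    specificity = vapply(f, `[`, "", 8),
    stringsAsFactors = FALSE
  )
  validate_segments(df)
  df
}

#' Validate segment annotations
#'
#' @param df Segment `data.frame` as returned by [read_segments()].
#' @return `df`, invisibly.
#' @export
validate_segments <- function(df) {
  validate_intervals(df)
  bad <- setdiff(unique(df$seg_class), SEG_CLASSES)
  if (length(bad))
    stop("unknown segment class: ", paste(bad, collapse = ", "))
  bad <- setdiff(unique(df$specificity), SEG_SPECIFICITIES)
  if (length(bad))
    stop("unknown segment specificity: ", paste(bad, collapse = ", "))
  # same-class segments must be disjoint
  for (cl in unique(df$seg_class)) {
    d <- df[df$seg_class == cl, ]
    for (ch in unique(d$chrom)) {
      dc <- d[d$chrom == ch, ]
      dc <- dc[order(dc$start), ]
      if (nrow(dc) > 1 && any(dc$start[-1] < dc$end[-nrow(dc)]))
        stop("overlapping ", cl, " segments on ", ch)
    }
  }
  invisible(df)
}

#' Write segment annotations as BED6+2
#'
#' @param segments Segment `data.frame`.
#' @param path Output file.
#' @return `path`, invisibly.
#' @export
write_segments <- function(segments, path) {
  validate_segments(segments)
  lines <- sprintf("%s\t%d\t%d\t%s\t%s\t%s\t%s\t%s",
                   segments$chrom, segments$start, segments$end,
                   segments$name %||% ".", format(segments$score %||% 0),
                   segments$strand, segments$seg_class, segments$specificity)
  writeLines(lines, path)
  invisible(path)
}

#' Read aligned reads (minimal SAM subset or 6-column TSV)
#'
#' The SAM subset is ungapped single-end records: POS is converted from
#' 1-based to the internal 0-based convention, the reference span is taken
#' from the SEQ length, strand from flag bit 0x10, and the number of reported
#' alignment positions from the `NH:i:` tag (missing NH means 1). Unmapped
#' records (flag 0x4) are skipped with a message. The TSV alternative has
#' columns `chrom`, `start` (0-based), `end`, `strand`, `read_id`, `n_hits`.
#'
#' @param path SAM or TSV file.
#' @param sample Sample label attached to every record.
#' @param format `"auto"`, `"sam"` or `"tsv"`.
#' @return `data.frame` with columns `chrom`, `start`, `end`, `strand`,
#'   `read_id`, `n_hits`, `sample` and, for SAM input, `seq`.
#' @export
read_alignments <- function(path, sample, format = c("auto", "sam", "tsv")) {
  format <- match.arg(format)
  lines <- readLines(path)
  if (format == "auto") {
    format <- if (grepl("\\.sam$", path) || any(startsWith(lines, "@")) ||
                  (length(lines) > 0 && length(strsplit(lines[1], "\t")[[1]]) >= 11))
      "sam" else "tsv"
  }
  if (format == "sam") {
    lines <- lines[!startsWith(lines, "@")]
    if (length(lines) == 0) return(empty_alignments(sample))
    f <- strsplit(lines, "\t")
    flag <- as.integer(vapply(f, `[`, "", 2))
    unmapped <- bitwAnd(flag, 4L) > 0L
    if (any(unmapped))
      message("skipped ", sum(unmapped), " unmapped records")
    f <- f[!unmapped]
    flag <- flag[!unmapped]
    if (length(f) == 0) return(empty_alignments(sample))
    pos <- as.integer(vapply(f, `[`, "", 4))
    if (any(is.na(pos) | pos < 1))
      stop("SAM format error: invalid POS")
    seqs <- toupper(vapply(f, `[`, "", 10))
    if (any(seqs == "*"))
      stop("SAM format error: SEQ required to determine reference span")
    nh <- vapply(f, function(x) {
      hit <- grep("^NH:i:", x, value = TRUE)
      if (length(hit)) as.integer(sub("^NH:i:", "", hit[1])) else 1L
    }, 0L)
    df <- data.frame(
      chrom = vapply(f, `[`, "", 3),
      start = pos - 1L,
      end = pos - 1L + nchar(seqs),
      strand = ifelse(bitwAnd(flag, 16L) > 0L, "-", "+"),
      read_id = vapply(f, `[`, "", 1),
      n_hits = nh,
      sample = sample,
      seq = seqs,
      stringsAsFactors = FALSE
    )
  } else {
    lines <- lines[nzchar(lines) & !startsWith(lines, "#")]
    if (length(lines) == 0) return(empty_alignments(sample))
    f <- strsplit(lines, "\t")
    if (any(lengths(f) < 6))
      stop("alignment TSV format error: expected 6 columns")
    df <- data.frame(
      chrom = vapply(f, `[`, "", 1),
      start = as.integer(vapply(f, `[`, "", 2)),
      end = as.integer(vapply(f, `[`, "", 3)),
      strand = vapply(f, `[`, "", 4),
      read_id = vapply(f, `[`, "", 5),
      n_hits = as.integer(vapply(f, `[`, "", 6)),
      sample = sample,
      stringsAsFactors = FALSE
    )
    if (any(df$start < 0)) stop("alignment TSV format error: negative start")
  }
  if (any(df$n_hits < 1)) stop("alignment error: n_hits must be >= 1")
  validate_intervals(df)
  df
}

empty_alignments <- function(sample) {
  data.frame(chrom = character(0), start = integer(0), end = integer(0),
             strand = character(0), read_id = character(0), n_hits = integer(0),
             sample = rep(sample, 0), stringsAsFactors = FALSE)
}

#' Write alignments as minimal SAM
#'
#' @param aln Alignment `data.frame` (as from [read_alignments()]); a `seq`
#'   column is used verbatim, otherwise `N` runs of the right length are
#'   emitted.
#' @param sizes Named integer vector of chromosome sizes for `@SQ` headers.
#' @param path Output file.
#' @return `path`, invisibly.
#' @export
write_sam <- function(aln, sizes, path) {
  hdr <- c("@HD\tVN:1.6\tSO:unsorted",
           sprintf("@SQ\tSN:%s\tLN:%d", names(sizes), as.integer(sizes)))
  seqs <- if ("seq" %in% names(aln)) aln$seq else strrep("N", aln$end - aln$start)
  rec <- sprintf("%s\t%d\t%s\t%d\t255\t%dM\t*\t0\t0\t%s\t*\tNH:i:%d",
                 aln$read_id, ifelse(aln$strand == "-", 16L, 0L), aln$chrom,
                 aln$start + 1L, aln$end - aln$start, seqs, aln$n_hits)
  writeLines(c(hdr, rec), path)
  invisible(path)
}

#' Write alignments as 6-column TSV
#'
#' @param aln Alignment `data.frame`.
#' @param path Output file.
#' @return `path`, invisibly.
#' @export
write_alignments_tsv <- function(aln, path) {
  writeLines(sprintf("%s\t%d\t%d\t%s\t%s\t%d", aln$chrom, aln$start, aln$end,
                     aln$strand, aln$read_id, aln$n_hits), path)
  invisible(path)
}

#' Write a bedGraph track
#'
#' Accepts either cytosine calls (columns `chrom`, `pos`, `meth_pct`; each
#' cytosine becomes a 1 bp record) or scored intervals (columns `chrom`,
#' `start`, `end`, `value`). Input must already be sorted by chromosome then
#' start; unsorted or interleaved input is an error rather than silently
#' reordered.
#'
#' @param x Calls or scored-interval `data.frame`.
#' @param path Output file.
#' @return `path`, invisibly.
#' @export
write_bedgraph <- function(x, path) {
  if ("pos" %in% names(x)) {
    x <- data.frame(chrom = x$chrom, start = x$pos, end = x$pos + 1L,
                    value = x$meth_pct, stringsAsFactors = FALSE)
  }
  if (nrow(x) > 0) {
    runs <- rle(x$chrom)
    if (anyDuplicated(runs$values))
      stop("unsorted input: chromosomes interleaved")
    for (ch in runs$values) {
      if (is.unsorted(x$start[x$chrom == ch]))
        stop("unsorted input: starts not increasing on ", ch)
    }
  }
  con <- file(path, "w")
  on.exit(close(con))
  writeLines("track type=bedGraph", con)
  if (nrow(x) > 0)
    writeLines(sprintf("%s\t%d\t%d\t%s", x$chrom, x$start, x$end,
                       formatC(signif(x$value, 6), format = "fg")), con)
  invisible(path)
}

#' Read a position weight matrix from tab text
#'
#' One row per motif position with four tab-separated columns (A, C, G, T);
#' `#` lines are comments. Values may be probabilities or counts; rows are
#' pseudocount-regularized and renormalized by [pwm()].
#'
#' @param path PWM file.
#' @param ... Passed to [pwm()] (background, pseudocount).
#' @return A `pwm` object.
#' @export
read_pwm <- function(path, ...) {
  lines <- readLines(path)
  lines <- lines[nzchar(lines) & !startsWith(lines, "#")]
  mat <- do.call(rbind, lapply(strsplit(lines, "\t"), as.numeric))
  colnames(mat) <- c("A", "C", "G", "T")
  pwm(mat, ...)
}

#' Write result tables as TSV
#'
#' @param df Any `data.frame`.
#' @param path Output file.
#' @return `path`, invisibly.
#' @export
write_tsv <- function(df, path) {
  df <- as.data.frame(lapply(df, function(col) {
    if (is.list(col)) vapply(col, paste, "", collapse = ",") else col
  }), stringsAsFactors = FALSE, check.names = FALSE)
  names(df) <- names(df)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
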