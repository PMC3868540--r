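# Independent brute-force oracles used to cross-check the fast paths.

brute_count_windows <- function(tags, windows) {
  vapply(seq_len(nrow(windows)), function(w) {
    sel <- tags$chrom == windows$chrom[w] &
      tags$pos >= windows$start[w] & tags$pos < windows$end[w]
    sum(tags$weight[sel])
  }, 0)
}

# per-base boolean-array overlap on a small genome
brute_overlap_bases <- function(regions, segments, sizes) {
  tot <- 0L
  for (ch in names(sizes)) {
    a <- logical(sizes[[ch]])
    b <- logical(sizes[[ch]])
    r <- regions[regions$chrom == ch, , drop = FALSE]
    s <- segments[segments$chrom == ch, , drop = FALSE]
    for (i in seq_len(nrow(r))) a[(r$start[i] + 1):r$end[i]] <- TRUE
    for (i in seq_len(nrow(s))) b[(s$start[i] + 1):s$end[i]] <- TRUE
    tot <- tot + sum(a & b)
  }
  tot
}

# union-coverage merge of flagged windows, one class at a time
brute_merge <- function(windows, sizes) {
  out <- NULL
  for (ch in names(sizes)) {
    covered <- logical(sizes[[ch]])
    w <- windows[windows$chrom == ch, , drop = FALSE]
    for (i in seq_len(nrow(w))) covered[(w$start[i] + 1):w$end[i]] <- TRUE
    r <- rle(covered)
    ends <- cumsum(r$lengths)
    starts <- ends - r$lengths
    keep <- r$values
    if (any(keep))
      out <- rbind(out, data.frame(chrom = ch, start = starts[keep],
                                   end = ends[keep]))
  }
  if (is.null(out))
    out <- data.frame(chrom = character(0), start = integer(0), end = integer(0))
  rownames(out) <- NULL
  out
}

# exhaustive gapped scan of one plus-strand sequence
brute_scan_gapped <- function(p, sequence, linker_range, linker_after) {
  n <- nchar(sequence)
  la <- linker_after
  left_seq <- function(t, l) substr(sequence, t, t + la - 1)
  best <- list()
  for (t in seq_len(n)) {
    bs <- -Inf
    bl <- NA_integer_
    for (l in sort(linker_range)) {
      w <- p$length + l
      if (t + w - 1 > n) next
      core <- paste0(substr(sequence, t, t + la - 1),
                     substr(sequence, t + la + l, t + w - 1))
      sc <- score_window(p, core)
      if (sc > bs) { bs <- sc; bl <- l }
    }
    best[[t]] <- c(score = bs, linker = bl)
  }
  data.frame(start = seq_len(n) - 1L,
             score = vapply(best, `[[`, 0, "score"),
             linker = vapply(best, `[[`, 0, "linker"))
}

random_intervals <- function(n, sizes, max_len = 200) {
  ch <- sample(names(sizes), n, replace = TRUE)
  len <- sample.int(max_len, n, replace = TRUE)
  start <- vapply(seq_len(n), function(i)
    sample.int(sizes[[ch[i]]] - len[i], 1) - 1L, 0L)
  data.frame(chrom = ch, start = start, end = start + len,
             stringsAsFactors = FALSE)
}
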