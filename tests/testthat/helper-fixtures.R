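# Small deterministic fixtures shared across tests.

uniform_pwm <- function(len = 4) {
  pwm(matrix(0.25, len, 4), pseudocount = 0)
}

toy_pwm <- function(consensus, strength = 0.85, pseudocount = 0.01) {
  chars <- strsplit(consensus, "")[[1]]
  mat <- matrix((1 - strength) / 3, length(chars), 4,
                dimnames = list(NULL, c("A", "C", "G", "T")))
  mat[cbind(seq_along(chars), match(chars, c("A", "C", "G", "T")))] <- strength
  pwm(mat, pseudocount = pseudocount)
}

# alignment frame helper
aln_df <- function(chrom, start, end, strand = "+", read_id = NULL,
                   n_hits = 1L, seq = NULL, sample = "s") {
  n <- length(start)
  df <- data.frame(chrom = rep_len(chrom, n), start = as.integer(start),
                   end = as.integer(end), strand = rep_len(strand, n),
                   read_id = read_id %||% sprintf("r%03d", seq_len(n)),
                   n_hits = rep_len(as.integer(n_hits), n),
                   sample = rep_len(sample, n), stringsAsFactors = FALSE)
  if (!is.null(seq)) df$seq <- seq
  df
}

`%||%` <- function(x, y) if (is.null(x)) y else x

calls_df <- function(chrom, pos, n_meth, n_total, strand = "+") {
  data.frame(chrom = rep_len(chrom, length(pos)), pos = as.integer(pos),
             strand = rep_len(strand, length(pos)),
             n_meth = as.integer(n_meth), n_total = as.integer(n_total),
             meth_pct = 100 * n_meth / n_total, stringsAsFactors = FALSE)
}
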