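test_that("log-odds scoring matches closed forms", {
  # uniform matrix scores 0 for any sequence
  expect_equal(score_window(uniform_pwm(4), "ACGT"), 0)
  expect_equal(score_window(uniform_pwm(4), "TTTT"), 0)

  # single position, p(A)=0.5 vs background 0.25 -> exactly 1 bit
  p1 <- pwm(matrix(c(0.5, 1/6, 1/6, 1/6), 1, 4), pseudocount = 0)
  expect_equal(score_window(p1, "A"), 1.0)

  # N bases yield the -Inf sentinel; length mismatch is an error
  expect_identical(score_window(uniform_pwm(4), "ACNT"), -Inf)
  expect_error(score_window(uniform_pwm(4), "ACGTA"), "length")
})

test_that("ungapped scan maximum equals an exhaustive per-window oracle", {
  set.seed(42)
  p <- toy_pwm(paste(sample(c("A", "C", "G", "T"), 8, TRUE), collapse = ""))
  g <- list(chr1 = paste(sample(c("A", "C", "G", "T"), 1000, TRUE),
                         collapse = ""))
  hits <- scan_pwm(p, g, threshold = -Inf, resolve_overlaps = FALSE)
  plus <- hits[hits$strand == "+", ]
  oracle <- vapply(seq_len(1000 - 8 + 1), function(t)
    score_window(p, substr(g$chr1, t, t + 7)), 0)
  expect_equal(nrow(plus), length(oracle))
  expect_equal(plus$score[order(plus$start)], oracle)
  expect_equal(max(hits$score), max(oracle) ) # best over strands >= plus max
})

test_that("strand symmetry: a hit's reverse complement scores the same on the other strand", {
  p <- toy_pwm("ACGGTTCA")
  site <- "ACGGTTCA"
  rc <- chartr("ACGT", "TGCA", paste(rev(strsplit(site, "")[[1]]), collapse = ""))
  g_fwd <- list(chr1 = paste0("TTTTTTTTTT", site, "TTTTTTTTTT"))
  g_rev <- list(chr1 = paste0("AAAAAAAAAA", rc, "AAAAAAAAAA"))
  h_fwd <- scan_pwm(p, g_fwd, threshold = 5)
  h_rev <- scan_pwm(p, g_rev, threshold = 5)
  expect_equal(h_fwd$score[h_fwd$strand == "+"],
               h_rev$score[h_rev$strand == "-"])
  expect_equal(h_rev$start[h_rev$strand == "-"], 10)
})

test_that("gapped scan reduces to ungapped at linker 0 and recovers planted linkers", {
  p <- example_pwm("rest_like")
  set.seed(7)
  g <- make_genome(n_chrom = 1, chrom_len = 20000, gc = 0.42, seed = 3)
  # linker_range = {0} must reproduce the ungapped scan exactly
  ungapped <- scan_pwm(p, g$seqs, threshold = -Inf, resolve_overlaps = FALSE)
  gapped0 <- scan_pwm(p, g$seqs, threshold = -Inf, linker_range = 0,
                      linker_after = 9, resolve_overlaps = FALSE)
  expect_equal(gapped0$score, ungapped$score)
  expect_true(all(gapped0$linker_len == 0))

  planted <- plant_motifs(g, p, sites = data.frame(chrom = "chr1",
                                                   start = c(2000, 9000)),
                          mode = "consensus", linker_range = 7,
                          linker_after = 9, seed = 5)
  hits <- scan_pwm(p, planted$seqs, threshold = 15, linker_range = 0:11,
                   linker_after = 9)
  rec <- merge(planted$truth[c("chrom", "start", "linker_len")],
               hits[c("chrom", "start", "linker_len")], by = c("chrom", "start"))
  expect_equal(nrow(rec), 2)
  expect_equal(rec$linker_len.y, rec$linker_len.x)
})

test_that("gapped scores equal brute-force enumeration over linker lengths", {
  p <- toy_pwm("ACGTAC")
  la <- 3
  set.seed(11)
  for (rep in 1:5) {
    s <- paste(sample(c("A", "C", "G", "T"), 120, TRUE), collapse = "")
    hits <- scan_pwm(p, list(chr1 = s), threshold = -Inf,
                     linker_range = 0:4, linker_after = la,
                     resolve_overlaps = FALSE)
    plus <- hits[hits$strand == "+", ]
    oracle <- brute_scan_gapped(p, s, 0:4, la)
    oracle <- oracle[is.finite(oracle$score), ]
    m <- merge(plus, oracle, by = "start")
    expect_equal(nrow(m), nrow(plus))
    expect_equal(m$score.x, m$score.y)
    expect_equal(m$linker_len, m$linker)  # smallest linker wins ties
  }
})

test_that("raising the threshold never adds hits", {
  p <- toy_pwm("ACGTACGT")
  g <- make_genome(n_chrom = 1, chrom_len = 5000, seed = 9)$seqs
  lo <- scan_pwm(p, g, threshold = -5, resolve_overlaps = FALSE)
  hi <- scan_pwm(p, g, threshold = 5, resolve_overlaps = FALSE)
  expect_true(nrow(hi) <= nrow(lo))
  key <- function(h) paste(h$chrom, h$start, h$strand)
  expect_true(all(key(hi) %in% key(lo)))
  expect_warning(none <- scan_pwm(p, g, threshold = 1e6), "no hits")
  expect_equal(nrow(none), 0)
})

test_that("CpG annotation records plus-strand C offsets within the match", {
  g <- list(chr1 = "TTAACGTTCGCG")
  hits <- data.frame(chrom = "chr1", start = 2L, end = 8L, strand = "+",
                     stringsAsFactors = FALSE)
  ann <- annotate_cpg(hits, g)
  expect_equal(ann$cpg_offsets[[1]], 2L)  # "AACGTT" -> C of CG at offset 2

  hits2 <- data.frame(chrom = "chr1", start = 0L, end = 4L, strand = "+")
  expect_equal(annotate_cpg(hits2, g)$cpg_offsets[[1]], integer(0))

  # offset predicate
  expect_true(cpg_at_offsets(ann, 2L))
  expect_false(cpg_at_offsets(ann, 0L))
})

test_that("motif centers use the floor(width/2) convention", {
  h <- data.frame(chrom = "chr1", start = c(10L, 10L), end = c(30L, 31L))
  expect_equal(motif_center(h), c(20L, 20L))
})

test_that("planted consensus motifs are recovered by scanning", {
  g <- make_genome(n_chrom = 2, chrom_len = 150000, seed = 21)
  p <- example_pwm("ctcf_like")
  planted <- plant_motifs(g, p, sites = 100, mode = "consensus",
                          min_spacing = 800, seed = 22)
  thr <- min(planted$truth$score) - 1
  hits <- scan_pwm(p, planted$seqs, threshold = thr)
  key <- function(d) paste(d$chrom, d$start)
  recovered <- sum(key(planted$truth) %in% key(hits))
  expect_gte(recovered, 99)
})
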