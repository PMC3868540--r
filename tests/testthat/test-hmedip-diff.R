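test_that("the fold-change formula matches hand evaluation and its limits", {
  # n_NP=100, n_ES=10, equal libraries of 1e6, p=8: log2(108/18) = log2(6)
  expect_equal(log2fc(10, 100, 1e6, 1e6, 8), log2(6))
  # equal counts and libraries -> 0
  expect_equal(log2fc(55, 55, 1e6, 1e6, 8), 0)
  # growing pseudocount shrinks |log2FC| monotonically to 0
  ps <- c(1, 8, 64, 512, 4096)
  v <- vapply(ps, function(p) log2fc(10, 100, 1e5, 1e5, p), 0)
  expect_true(all(diff(abs(v)) < 0))
  expect_lt(abs(v[length(v)]), 0.05)
  expect_error(log2fc(1, 1, 0, 10, 8), "library")
  expect_error(log2fc(Inf, 1, 10, 10, 8), "finite")
})

test_that("fold change is antisymmetric under swapping conditions", {
  set.seed(61)
  for (i in 1:200) {
    n1 <- runif(1, 0, 500); n2 <- runif(1, 0, 500)
    N1 <- runif(1, 1e4, 1e6); N2 <- runif(1, 1e4, 1e6)
    expect_equal(log2fc(n1, n2, N1, N2, 8), -log2fc(n2, n1, N2, N1, 8))
  }
})

test_that("genome tiling follows the published phase and partial-window rule", {
  w <- tile_genome(c(chrA = 2500L), 1000, 500)
  expect_equal(w$start, c(0L, 500L, 1000L, 1500L))
  expect_equal(w$end, c(1000L, 1500L, 2000L, 2500L))
  # a trailing partial that extends coverage is kept
  w2 <- tile_genome(c(chrA = 2400L), 1000, 500)
  expect_equal(w2$start, c(0L, 500L, 1000L, 1500L))
  expect_equal(w2$end[4], 2400L)
  # chromosome shorter than a window but >= step
  w3 <- tile_genome(c(chrA = 700L), 1000, 500)
  expect_equal(w3$start, 0L)
  expect_equal(w3$end, 700L)
  expect_equal(nrow(tile_genome(c(chrA = 400L), 1000, 500)), 0)
  expect_error(fc_params(step = 1500), "step")
  expect_error(fc_params(p = 0), "p must")
})

test_that("window scanning yields zero fold change without tags and matches recounts", {
  sizes <- c(chr1 = 5000L)
  empty <- data.frame(chrom = character(0), pos = integer(0),
                      weight = numeric(0), read_id = character(0))
  one <- data.frame(chrom = "chr1", pos = 10L, weight = 1, read_id = "r")
  ws <- window_scan(one, one, sizes, fc_params())
  expect_true(all(ws$log2fc == 0))
  set.seed(62)
  t_es <- data.frame(chrom = "chr1", pos = sample.int(5000, 800) - 1L,
                     weight = 1 / sample.int(3, 800, TRUE),
                     read_id = sprintf("e%04d", 1:800))
  t_np <- data.frame(chrom = "chr1", pos = sample.int(5000, 600) - 1L,
                     weight = 1, read_id = sprintf("n%04d", 1:600))
  ws2 <- window_scan(t_es, t_np, sizes, fc_params())
  expect_equal(ws2$n_ES, brute_count_windows(t_es, ws2))
  expect_equal(ws2$n_NP, brute_count_windows(t_np, ws2))
  expect_equal(ws2$log2fc,
               log2fc(ws2$n_ES, ws2$n_NP, sum(t_es$weight), sum(t_np$weight), 8))
})

test_that("the dual-replicate rule uses strict inequalities in both replicates", {
  tiling <- data.frame(chrom = "chr1", start = c(0L, 500L, 1000L, 1500L),
                       end = c(1000L, 1500L, 2000L, 2500L))
  mk <- function(fc) cbind(tiling, log2fc = fc)
  fl <- consistent_windows(mk(c(3.5, 3.5, 3.5, 3.0)),
                           mk(c(3.2, 2.9, -3.5, 3.2)), 3)
  expect_equal(fl$flag, c("gain", "none", "none", "none"))
  fl2 <- consistent_windows(mk(c(-3.5, -3.1)[c(1, 2, 1, 2)]),
                            mk(c(-4, -3.01)[c(1, 2, 1, 2)]), 3)
  expect_true(all(fl2$flag == "loss"))
  expect_error(consistent_windows(mk(1:4), mk(1:4)[c(2, 1, 3, 4), ], 3),
               "tilings differ")
})

test_that("region merging joins overlapping and book-ended windows per class", {
  fl <- data.frame(chrom = "chr1",
                   start = c(0L, 500L, 500L, 3000L),
                   end = c(1000L, 1500L, 1500L, 4000L),
                   flag = c("gain", "gain", "loss", "gain"))
  r <- merge_regions(fl)
  expect_equal(r$gain$start, c(0L, 3000L))
  expect_equal(r$gain$end, c(1500L, 4000L))
  expect_equal(r$loss$start, 500L)   # loss untouched by gain merge

  # book-ended windows merge
  fl2 <- data.frame(chrom = "chr1", start = c(0L, 1000L), end = c(1000L, 2000L),
                    flag = "gain")
  expect_equal(merge_regions(fl2)$gain$end, 2000L)
})

test_that("merging matches a union-coverage oracle on random flag sets", {
  set.seed(63)
  sizes <- c(chr1 = 20000L, chr2 = 15000L)
  tiling <- tile_genome(sizes, 1000, 500)
  for (rep in 1:20) {
    fl <- tiling
    fl$flag <- sample(c("gain", "loss", "none"), nrow(fl), TRUE,
                      prob = c(0.2, 0.2, 0.6))
    got <- merge_regions(fl)
    for (cl in c("gain", "loss")) {
      want <- brute_merge(fl[fl$flag == cl, ], sizes)
      expect_equal(got[[cl]]$start, want$start)
      expect_equal(got[[cl]]$end, want$end)
    }
  }
})

test_that("swapping condition labels maps gains to losses exactly", {
  set.seed(64)
  sizes <- c(chr1 = 30000L)
  mk_tags <- function(n, seed) {
    set.seed(seed)
    data.frame(chrom = "chr1", pos = sample.int(30000, n) - 1L,
               weight = 1, read_id = sprintf("t%05d", seq_len(n)))
  }
  e1 <- mk_tags(2000, 1); n1 <- mk_tags(500, 2)
  e2 <- mk_tags(1900, 3); n2 <- mk_tags(550, 4)
  fwd <- consistent_windows(window_scan(e1, n1, sizes),
                            window_scan(e2, n2, sizes), 1)
  rev <- consistent_windows(window_scan(n1, e1, sizes),
                            window_scan(n2, e2, sizes), 1)
  expect_equal(fwd$flag == "gain", rev$flag == "loss")
  expect_equal(fwd$flag == "loss", rev$flag == "gain")
  expect_equal(merge_regions(fwd)$gain, merge_regions(rev)$loss)
})
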