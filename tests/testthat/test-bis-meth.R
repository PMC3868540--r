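test_that("per-cytosine counting follows the C/T and G/A rules", {
  g <- list(chr1 = "TTACGTTTTT")   # CpG: C at 3, G at 4
  # ten plus-strand reads, all retaining C
  rd <- aln_df("chr1", rep(0, 10), rep(10, 10), seq = rep("TTACGTTTTT", 10))
  calls <- extract_methylation(rd, g)
  expect_equal(calls$n_meth, 10L)
  expect_equal(calls$n_total, 10L)
  expect_equal(calls$meth_pct, 100)

  # 5 converted, 5 retained -> 50%
  rd2 <- aln_df("chr1", rep(0, 10), rep(10, 10),
                seq = c(rep("TTACGTTTTT", 5), rep("TTATGTTTTT", 5)))
  expect_equal(extract_methylation(rd2, g)$meth_pct, 50)

  # minus-strand reads report G (methylated) / A (converted) at pos 4
  rd3 <- aln_df("chr1", rep(0, 4), rep(10, 4), strand = "-",
                seq = c("TTACGTTTTT", "TTACGTTTTT", "TTACATTTTT",
                        "TTACATTTTT"))
  c3 <- extract_methylation(rd3, g)
  expect_equal(c3$strand, "-")
  expect_equal(c3$pos, 4L)
  expect_equal(c3$meth_pct, 50)

  # mismatching bases are excluded and counted
  rd4 <- aln_df("chr1", 0, 10, seq = "TTAGGTTTTT")
  c4 <- extract_methylation(rd4, g)
  expect_equal(nrow(c4), 0)
  expect_equal(attr(c4, "mismatches"), 1L)

  expect_error(extract_methylation(aln_df("chr1", 5, 15, seq = "AAAAAAAAAA"), g),
               "outside")
})

test_that("no base is counted twice and totals are conserved", {
  g <- make_genome(n_chrom = 1, chrom_len = 20000, seed = 41)
  p <- example_pwm("ctcf_like")
  planted <- plant_motifs(g, p, sites = 5, min_spacing = 1600,
                          mode = "consensus", seed = 42)
  gen <- planted[c("seqs", "sizes", "cpg")]
  cfg <- scenario_config("unlinked", demeth = 0.5, seed = 43)
  mols <- simulate_molecules(planted$truth, gen, cfg, n_molecules = 50)
  rd <- simulate_bisulfite_reads(gen, mols, depth = 20, seed = 44)
  calls <- extract_methylation(rd, gen$seqs, gen$cpg)
  expect_true(all(calls$n_meth <= calls$n_total))
  # total observations cannot exceed reads x max CpGs per read
  expect_lte(sum(calls$n_total), nrow(rd) * 50)
  # per-position totals match a direct per-read recount at one position
  i <- which(calls$strand == "+")[1]
  covering <- sum(rd$strand == "+" & rd$start <= calls$pos[i] &
                    rd$end > calls$pos[i])
  expect_equal(calls$n_total[i], covering)
})

test_that("coverage filtering applies the 10x boundary and the joint rule", {
  calls <- calls_df("chr1", 1:7, 0, c(3, 10, 11, 9, 10, 25, 0))
  kept <- filter_coverage(calls, min_cov = 10)
  expect_equal(nrow(kept), 4)            # hand count: {10,11,10,25}
  expect_equal(kept$n_total, c(10L, 11L, 10L, 25L))

  wg <- calls_df("chr1", 100, 6, 12)
  chip <- calls_df("chr1", 100, 2, 8)
  expect_equal(nrow(filter_coverage(wg, 10, joint_with = chip)), 0)
  chip2 <- calls_df("chr1", 100, 2, 10)
  expect_equal(nrow(filter_coverage(wg, 10, joint_with = chip2)), 1)
})

test_that("window methylation averages are coverage-weighted by default", {
  calls <- calls_df("chr1", c(100, 120), c(10, 0), c(10, 10))
  ctr <- data.frame(chrom = "chr1", center = 110L)
  expect_equal(window_methylation(calls, ctr), 50)
  expect_equal(window_methylation(calls[1, ], ctr), 100)
  # weighted vs unweighted diverge with unequal coverage
  calls2 <- calls_df("chr1", c(100, 120), c(30, 0), c(30, 10))
  expect_equal(window_methylation(calls2, ctr), 75)
  expect_equal(window_methylation(calls2, ctr, weighted = FALSE), 50)
  # empty window yields the NA sentinel
  expect_true(is.na(window_methylation(calls, data.frame(chrom = "chr1",
                                                         center = 5000L))))
})

test_that("window methylation equals explicit summation on random fixtures", {
  set.seed(45)
  for (rep in 1:20) {
    n <- 30
    calls <- calls_df("chr1", sample.int(2000, n),
                      n_meth = rbinom(n, 20, 0.4), n_total = 20)
    ctr <- data.frame(chrom = "chr1", center = sample.int(2000, 5))
    got <- window_methylation(calls, ctr, width = 200)
    for (i in 1:5) {
      sel <- calls$pos >= ctr$center[i] - 100 & calls$pos < ctr$center[i] + 100
      want <- if (any(sel)) 100 * sum(calls$n_meth[sel]) / sum(calls$n_total[sel])
              else NA_real_
      expect_equal(got[i], want)
    }
  }
})

test_that("strand collapsing pools CpG pairs", {
  calls <- rbind(calls_df("chr1", 10, 3, 10, "+"),
                 calls_df("chr1", 11, 5, 10, "-"))
  col <- collapse_strands(calls)
  expect_equal(nrow(col), 1)
  expect_equal(col$pos, 10L)
  expect_equal(col$n_meth, 8L)
  expect_equal(col$n_total, 20L)
})

test_that("deep coverage converges to the planted molecule-level mean", {
  g <- make_genome(n_chrom = 1, chrom_len = 30000, seed = 46)
  p <- example_pwm("ctcf_like")
  planted <- plant_motifs(g, p, sites = 8, min_spacing = 1800,
                          mode = "consensus", seed = 47)
  gen <- planted[c("seqs", "sizes", "cpg")]
  cfg <- scenario_config("static", occupancy = 0.6, seed = 48)
  mols <- simulate_molecules(planted$truth, gen, cfg, n_molecules = 2000)
  rd <- simulate_bisulfite_reads(gen, mols, read_len = 25, depth = 300,
                                 conversion_rate = 1, seed = 49)
  calls <- extract_methylation(rd, gen$seqs, gen$cpg)
  for (i in seq_along(mols)) {
    s <- mols[[i]]
    if (!length(s$cpg_pos)) next
    planted_mean <- 100 * mean(s$meth != "U")
    sel <- calls$chrom == s$chrom & calls$pos >= s$region_start &
      calls$pos < s$region_end
    got <- 100 * sum(calls$n_meth[sel]) / sum(calls$n_total[sel])
    expect_lt(abs(got - planted_mean), 2)
  }
})
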