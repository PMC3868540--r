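test_that("genome generation is seed-deterministic and respects GC limits", {
  g1 <- make_genome(n_chrom = 2, chrom_len = 5000, seed = 1)
  g2 <- make_genome(n_chrom = 2, chrom_len = 5000, seed = 1)
  expect_identical(g1$seqs, g2$seqs)
  g3 <- make_genome(n_chrom = 2, chrom_len = 5000, seed = 2)
  expect_false(identical(g1$seqs, g3$seqs))

  g0 <- make_genome(n_chrom = 1, chrom_len = 2000, gc = 0, seed = 1)
  expect_false(grepl("[CG]", g0$seqs[[1]]))
  expect_equal(nrow(g0$cpg), 0)
  expect_error(make_genome(gc = 1.5), "gc")
})

test_that("the CpG table equals a direct dinucleotide scan", {
  g <- make_genome(n_chrom = 2, chrom_len = 50000, seed = 4)
  for (ch in names(g$seqs)) {
    m <- gregexpr("CG", g$seqs[[ch]], fixed = TRUE)[[1]]
    expected <- if (m[1] == -1) integer(0) else as.integer(m) - 1L
    expect_equal(g$cpg$pos[g$cpg$chrom == ch], expected)
  }
})

test_that("motif planting writes the expected sequence and truth table", {
  g <- make_genome(n_chrom = 1, chrom_len = 5000, seed = 5)
  p <- example_pwm("ctcf_like")
  planted <- plant_motifs(g, p, sites = data.frame(chrom = "chr1", start = 100),
                          mode = "consensus", seed = 6)
  expect_equal(substr(planted$seqs[[1]], 101, 120), pwm_consensus(p))
  expect_equal(planted$truth$end - planted$truth$start, 20L)
  expect_equal(planted$truth$cpg_offsets[[1]], 4L)  # consensus CpG at 5-6

  # gapped planting with linker 0 has width = left + right parts
  pr <- example_pwm("rest_like")
  pl0 <- plant_motifs(g, pr, sites = data.frame(chrom = "chr1", start = 1000),
                      mode = "consensus", linker_range = 0, linker_after = 9,
                      seed = 7)
  expect_equal(pl0$truth$end - pl0$truth$start, pr$length)
  expect_error(plant_motifs(g, p, sites = data.frame(chrom = "chr1",
                                                     start = 4995),
                            seed = 8),
               "beyond")
})

test_that("molecule simulation honors the static and unlinked scenarios", {
  g <- make_genome(n_chrom = 1, chrom_len = 60000, seed = 9)
  p <- example_pwm("ctcf_like")
  planted <- plant_motifs(g, p, sites = 20, mode = "consensus",
                          min_spacing = 1500, seed = 10)
  gen <- planted[c("seqs", "sizes", "cpg")]

  cfg <- scenario_config("static", occupancy = 0.7, seed = 11)
  mols <- simulate_molecules(planted$truth, gen, cfg, n_molecules = 10000)
  meth <- molecule_methylation(mols)
  expect_true(all(abs(meth - 30) < 3, na.rm = TRUE))  # 1 - occupancy
  # bound molecules are fully unmethylated under static coupling
  s <- mols[[1]]
  expect_true(all(s$meth[s$bound, ] == "U"))
  expect_true(all(s$meth[!s$bound, ] %in% c("M", "H")))

  cfg1 <- scenario_config("static", occupancy = 1, seed = 12)
  m1 <- simulate_molecules(planted$truth[1, ], gen, cfg1, n_molecules = 50)
  expect_true(all(m1[[1]]$meth == "U"))

  cfgu <- scenario_config("unlinked", demeth = 0.7, seed = 13)
  mu <- simulate_molecules(planted$truth, gen, cfgu, n_molecules = 5000)
  su <- mu[[2]]
  bound_meth <- mean(su$meth[su$bound, ] != "U")
  pop_meth <- mean(su$meth != "U")
  expect_lt(abs(bound_meth - pop_meth), 0.05)  # independence of binding

  expect_error(scenario_config("static", occupancy = 1.2), "probabilities")
})

test_that("bisulfite conversion follows molecule state at conversion rate 1", {
  g <- make_genome(n_chrom = 1, chrom_len = 30000, seed = 14)
  p <- example_pwm("ctcf_like")
  planted <- plant_motifs(g, p, sites = 5, min_spacing = 2000,
                          mode = "consensus", seed = 15)
  gen <- planted[c("seqs", "sizes", "cpg")]

  # all-methylated molecules: reads match the reference at CpG cytosines
  cfgM <- scenario_config("static", occupancy = 0, seed = 16)  # all M
  molsM <- simulate_molecules(planted$truth, gen, cfgM, n_molecules = 20)
  rdM <- simulate_bisulfite_reads(gen, molsM, depth = 10, conversion_rate = 1,
                                  mode = "wg", seed = 17)
  callsM <- extract_methylation(rdM, gen$seqs, gen$cpg)
  expect_true(all(callsM$meth_pct == 100))

  # all-unmethylated molecules: every CpG C read as T
  cfgU <- scenario_config("static", occupancy = 1, seed = 18)
  molsU <- simulate_molecules(planted$truth, gen, cfgU, n_molecules = 20)
  rdU <- simulate_bisulfite_reads(gen, molsU, depth = 10, conversion_rate = 1,
                                  mode = "wg", seed = 19)
  callsU <- extract_methylation(rdU, gen$seqs, gen$cpg)
  expect_true(all(callsU$meth_pct == 0))

  expect_warning(simulate_bisulfite_reads(gen, molsU, depth = 0), "depth")
  expect_error(simulate_bisulfite_reads(gen, molsU, conversion_rate = 0),
               "conversion_rate")
})

test_that("methylation extracted at depth recovers the planted molecule mean", {
  g <- make_genome(n_chrom = 1, chrom_len = 60000, seed = 24)
  p <- example_pwm("ctcf_like")
  planted <- plant_motifs(g, p, sites = 15, min_spacing = 2000,
                          mode = "consensus", seed = 25)
  gen <- planted[c("seqs", "sizes", "cpg")]
  cfg <- scenario_config("unlinked", demeth = 0.6, seed = 26)
  mols <- simulate_molecules(planted$truth, gen, cfg, n_molecules = 500)
  rd <- simulate_bisulfite_reads(gen, mols, depth = 30, conversion_rate = 1,
                                 mode = "wg", seed = 27)
  calls <- extract_methylation(rd, gen$seqs, gen$cpg)
  planted_mean <- mean(molecule_methylation(mols), na.rm = TRUE)
  extracted <- 100 * sum(calls$n_meth) / sum(calls$n_total)
  expect_lt(abs(extracted - planted_mean), 3)
})

test_that("IP read sampling is uniform without signal and proportional with it", {
  sizes <- c(chr1 = 100000L)
  ip <- simulate_ip_reads(sizes, NULL, n_reads = 20000, background_frac = 1,
                          multihit_frac = 0, seed = 31)
  tags <- shift_and_weight(ip, 60, sizes)
  wins <- data.frame(chrom = "chr1", start = seq(0L, 90000L, 10000L),
                     end = seq(10000L, 100000L, 10000L))
  cts <- count_windows(tags, wins)
  expect_true(all(abs(cts - 2000) < 5 * sqrt(2000)))  # Poisson noise band

  sig <- data.frame(chrom = "chr1", start = c(0L, 10000L),
                    end = c(10000L, 20000L), weight = c(2, 1))
  ip2 <- simulate_ip_reads(sizes, sig, n_reads = 30000, background_frac = 0,
                           multihit_frac = 0, seed = 32)
  t2 <- shift_and_weight(ip2, 60, sizes)
  c2 <- count_windows(t2, wins[1:2, ])
  expect_lt(abs(c2[1] / c2[2] - 2), 0.15)

  expect_error(simulate_ip_reads(sizes, NULL, background_frac = 0),
               "all-zero")
})

test_that("multi-mapping decoys share read ids and conserve unit mass per read", {
  sizes <- c(chr1 = 50000L, chr2 = 50000L)
  ip <- simulate_ip_reads(sizes, NULL, n_reads = 2000, background_frac = 1,
                          multihit_frac = 0.2, multihit_max = 4, seed = 33)
  tags <- shift_and_weight(ip, 60, sizes)
  per_read <- tapply(tags$weight, tags$read_id, sum)
  expect_true(all(abs(per_read - 1) < 1e-9))
  expect_equal(sum(tags$weight), 2000)
  expect_true(any(ip$n_hits > 1))
})

test_that("generators are byte-deterministic under a fixed seed", {
  s1 <- sim_chipbis_study("static", n_sites = 5, depth = 10,
                          n_molecules = 40, seed = 34)
  s2 <- sim_chipbis_study("static", n_sites = 5, depth = 10,
                          n_molecules = 40, seed = 34)
  expect_identical(s1$wg, s2$wg)
  expect_identical(s1$chip, s2$chip)
  expect_identical(s1$genome$seqs, s2$genome$seqs)
})
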