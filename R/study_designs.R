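#' Example position weight matrices
#'
#' Ships two synthetic example matrices: a 20 bp ungapped CTCF-like motif
#' whose consensus carries a single CpG at motif positions 5-6 (1-based),
#' and a 21 bp REST-like motif meant to be scanned with a variable 0-11 nt
#' linker after position 9. These are illustrative stand-ins constructed for
#' this package, not the published matrices (which are inherited from prior
#' segmentation work and not restated here).
#'
#' @param name `"ctcf_like"` or `"rest_like"`.
#' @param strength Probability mass on the consensus base per position.
#' @return A `pwm` object.
#' @export
example_pwm <- function(name = c("ctcf_like", "rest_like"), strength = 0.85) {
  name <- match.arg(name)
  consensus <- switch(name,
    ctcf_like = "AGGTCGCTAGGTGCTAGCAT",   # CpG at positions 5-6
    rest_like = "TTCAGCACCACGGACAGCGCC"
  )
  chars <- strsplit(consensus, "")[[1]]
  mat <- matrix((1 - strength) / 3, length(chars), 4,
                dimnames = list(NULL, BASES))
  mat[cbind(seq_along(chars), match(chars, BASES))] <- strength
  pwm(mat)
}

#' Simulate a ChIP-BisSeq versus WG-BisSeq study
#'
#' The digital version of the bound-fraction experiment: a toy genome with
#' motif instances planted at LMR centers, per-molecule methylation states
#' drawn under the chosen scenario, and two bisulfite read sets — a
#' whole-genome library sampling all molecules and a ChIP library sampling
#' bound molecules (plus a small non-specific background). Optional allelic
#' DMR sites are simulated with deterministic coupling at 50% occupancy, so
#' the population is half methylated while the bound fraction is
#' unmethylated.
#'
#' Per-site occupancy (static) and demethylation (unlinked) probabilities
#' default to Uniform(0.5, 0.9) draws, giving ~30% marginal methylation
#' with between-site variation as seen across real LMRs.
#'
#' @param scenario `"static"` or `"unlinked"`.
#' @param n_sites Number of motif sites.
#' @param n_dmr Number of additional allelic DMR sites.
#' @param occupancy,demeth Per-site probabilities (scalar, vector, or NULL
#'   for the default draw).
#' @param n_molecules Molecules per site.
#' @param region_width Simulated region width per site, bp.
#' @param depth Bisulfite coverage per region.
#' @param read_len Read length, bp.
#' @param conversion_rate Bisulfite conversion rate.
#' @param chip_background Non-specific fraction of the ChIP library.
#' @param seed Integer seed.
#' @return List: `genome`, `truth` (regular sites), `dmr_truth`, `dmrs`
#'   (DMR intervals), `segments` (LMR annotations), `mols`, `wg`, `chip`
#'   alignment frames, and the configs used.
#' @export
sim_chipbis_study <- function(scenario = c("static", "unlinked"),
                              n_sites = 50, n_dmr = 0, occupancy = NULL,
                              demeth = NULL, n_molecules = 300,
                              region_width = 300, depth = 50, read_len = 50,
                              conversion_rate = 0.99, chip_background = 0.02,
                              seed = 1) {
  scenario <- match.arg(scenario)
  base <- make_genome(n_chrom = 2,
                      chrom_len = 60000 + (n_sites + n_dmr) * 2000,
                      gc = 0.42, seed = derive_seed(seed, 1))
  p <- example_pwm("ctcf_like")
  planted <- plant_motifs(base, p, sites = n_sites + n_dmr,
                          mode = "consensus", min_spacing = 1500,
                          seed = derive_seed(seed, 2))
  genome <- planted[c("seqs", "sizes", "cpg")]
  is_dmr <- rep(FALSE, nrow(planted$truth))
  if (n_dmr > 0)
    is_dmr[sample_dmr_rows(nrow(planted$truth), n_dmr, derive_seed(seed, 3))] <- TRUE
  truth <- planted$truth[!is_dmr, , drop = FALSE]
  dmr_truth <- planted$truth[is_dmr, , drop = FALSE]

  draw <- function(k, s) with_seed(s, stats::runif(k, 0.5, 0.9))
  if (is.null(occupancy)) occupancy <- draw(nrow(truth), derive_seed(seed, 4))
  if (is.null(demeth)) demeth <- draw(nrow(truth), derive_seed(seed, 5))
  cfg <- if (scenario == "static")
    scenario_config("static", occupancy = occupancy, seed = derive_seed(seed, 6))
  else
    scenario_config("unlinked", occupancy = occupancy, demeth = demeth,
                    seed = derive_seed(seed, 6))
  mols <- simulate_molecules(truth, genome, cfg, n_molecules, region_width)
  if (n_dmr > 0) {
    dmr_cfg <- scenario_config("static", occupancy = 0.5,
                               seed = derive_seed(seed, 7))
    dmr_mols <- simulate_molecules(dmr_truth, genome, dmr_cfg, n_molecules,
                                   region_width)
    mols <- structure(c(mols, dmr_mols), class = "molecule_sim")
  }
  wg <- simulate_bisulfite_reads(genome, mols, read_len, depth,
                                 conversion_rate, mode = "wg",
                                 sample_id = "wg", seed = derive_seed(seed, 8))
  chip <- simulate_bisulfite_reads(genome, mols, read_len, depth,
                                   conversion_rate, mode = "chip",
                                   chip_background = chip_background,
                                   sample_id = "chip",
                                   seed = derive_seed(seed, 9))
  all_truth <- rbind(truth[names(truth) != "cpg_offsets"],
                     dmr_truth[names(dmr_truth) != "cpg_offsets"])
  centers <- motif_center(all_truth)
  segments <- data.frame(
    chrom = all_truth$chrom, start = pmax(0L, centers - 500L),
    end = pmin(genome$sizes[all_truth$chrom], centers + 500L),
    name = sprintf("lmr%03d", seq_along(centers)), score = 0, strand = ".",
    seg_class = "LMR", specificity = "constitutive", stringsAsFactors = FALSE
  )
  dmrs <- if (n_dmr > 0) {
    dc <- motif_center(dmr_truth)
    data.frame(chrom = dmr_truth$chrom, start = dc - 100L, end = dc + 100L)
  } else data.frame(chrom = character(0), start = integer(0), end = integer(0))
  list(scenario = scenario, genome = genome, truth = truth,
       dmr_truth = dmr_truth, dmrs = dmrs, segments = segments, mols = mols,
       wg = wg, chip = chip, config = cfg, occupancy = occupancy,
       demeth = demeth)
}

sample_dmr_rows <- function(n, k, seed) with_seed(seed, sample.int(n, k))

#' Compare bound-fraction and population methylation
#'
#' Runs the full ChIP-BisSeq versus WG-BisSeq comparison on a
#' [sim_chipbis_study()] dataset: methylation extraction in both samples,
#' 200 bp windows centered at the planted motifs under the joint coverage
#' rule, the deviation/correlation summary, the DMR check, and the
#' per-cytosine distance-to-motif analysis.
#'
#' @param study Output of [sim_chipbis_study()].
#' @param min_cov Joint coverage threshold (default 10).
#' @param width Window width, bp.
#' @return List: `pairs` (window unit), `deviation` (on non-DMR windows),
#'   `dmr` summary, `cyt_pairs`, `distance` table (attribute `pearson_r`).
#' @export
analyze_chipbis <- function(study, min_cov = 10, width = 200) {
  wg_calls <- extract_methylation(study$wg, study$genome$seqs, study$genome$cpg)
  chip_calls <- extract_methylation(study$chip, study$genome$seqs,
                                    study$genome$cpg)
  hits_all <- rbind(study$truth[names(study$truth) != "cpg_offsets"],
                    study$dmr_truth[names(study$dmr_truth) != "cpg_offsets"])
  pairs <- paired_table(wg_calls, chip_calls, hits_all, unit = "window200",
                        min_cov = min_cov, width = width)
  non_dmr <- if (nrow(study$dmrs)) {
    loci <- data.frame(chrom = pairs$chrom, start = pairs$start,
                       end = pairs$end)
    ov <- overlap_pairs(loci, study$dmrs)
    pairs[setdiff(seq_len(nrow(pairs)), unique(ov$query)), , drop = FALSE]
  } else pairs
  deviation <- mean_deviation(non_dmr)
  dmr <- if (nrow(study$dmrs)) dmr_check(pairs, study$dmrs) else NULL
  cyt <- paired_table(wg_calls, chip_calls, hits_all, unit = "cytosine",
                      min_cov = min_cov)
  dist <- distance_delta(cyt, study$truth)
  list(pairs = pairs, deviation = deviation, dmr = dmr, cyt_pairs = cyt,
       distance = dist, wg_calls = wg_calls, chip_calls = chip_calls)
}

#' Simulate a binding-strength gradient study
#'
#' Motif sites spanning a gradient (or tiers) of occupancy, with
#' deterministically coupled methylation (`meth = 1 - occupancy`), an IP
#' library whose site signal is proportional to occupancy over a uniform
#' background, a uniform control (input) library, and a whole-genome
#' bisulfite library. The IP track is a uniform genome-wide background of
#' weight 1 with `amplitude x occupancy` stacked on each 200 bp site
#' window, so the IP-over-input density ratio at a site is close to
#' `1 + amplitude x occupancy`; the default amplitude of 24 places the 0 /
#' 0.3 / 0.9 occupancy tiers well inside the unbound / weak / strong
#' enrichment bands of the default class thresholds.
#'
#' @param n_sites Number of motif sites (ignored when `occupancy` given).
#' @param occupancy Per-site occupancies; default Uniform(0, 1) draws.
#' @param expected_class Optional per-site class labels for accuracy
#'   scoring (`"unbound"`, `"weak"`, `"strong"`).
#' @param amplitude IP signal weight per unit occupancy (relative to the
#'   uniform background weight of 1).
#' @param ip_reads Reads per IP/control library.
#' @param background_frac Non-specific fraction of the IP library.
#' @param depth Bisulfite coverage.
#' @param seed Integer seed.
#' @return List with `genome`, `truth` (incl. `occupancy`), `wg`, `ip`,
#'   `control` alignments and the design parameters.
#' @export
sim_gradient_study <- function(n_sites = 300, occupancy = NULL,
                               expected_class = NULL, amplitude = 24,
                               ip_reads = 200000, depth = 30, seed = 1) {
  if (is.null(occupancy))
    occupancy <- with_seed(derive_seed(seed, 1), stats::runif(n_sites))
  n_sites <- length(occupancy)
  base <- make_genome(n_chrom = 2, chrom_len = ceiling(n_sites / 2) * 3400,
                      gc = 0.42, seed = derive_seed(seed, 2))
  p <- example_pwm("ctcf_like")
  planted <- plant_motifs(base, p, sites = n_sites, mode = "consensus",
                          min_spacing = 1000, seed = derive_seed(seed, 3))
  genome <- planted[c("seqs", "sizes", "cpg")]
  truth <- planted$truth
  truth$occupancy <- occupancy
  if (!is.null(expected_class)) truth$expected_class <- expected_class
  cfg <- scenario_config("static", occupancy = occupancy,
                         seed = derive_seed(seed, 4))
  mols <- simulate_molecules(truth, genome, cfg, n_molecules = 300,
                             region_width = 300)
  wg <- simulate_bisulfite_reads(genome, mols, read_len = 50, depth = depth,
                                 conversion_rate = 0.99, mode = "wg",
                                 sample_id = "wg", seed = derive_seed(seed, 5))
  centers <- motif_center(truth)
  bg_track <- data.frame(chrom = names(genome$sizes), start = 0L,
                         end = as.integer(genome$sizes), weight = 1)
  signal <- rbind(bg_track,
                  data.frame(chrom = truth$chrom, start = centers - 100L,
                             end = centers + 100L,
                             weight = amplitude * occupancy))
  ip <- simulate_ip_reads(genome$sizes, signal, n_reads = ip_reads,
                          background_frac = 0,
                          sample_id = "ip", seed = derive_seed(seed, 6))
  control <- simulate_ip_reads(genome$sizes, NULL, n_reads = ip_reads,
                               background_frac = 1, sample_id = "input",
                               seed = derive_seed(seed, 7))
  list(genome = genome, truth = truth, mols = mols, wg = wg, ip = ip,
       control = control, amplitude = amplitude)
}

#' Relate binding strength to motif-CpG methylation
#'
#' Quantifies ChIP enrichment in 200 bp windows at each motif, classifies
#' sites into unbound/weak/strong, extracts strand-collapsed methylation of
#' CpGs inside the motif (coverage >= `min_cov`), and overlays the running
#' mean of methylation along the enrichment axis.
#'
#' @param study Output of [sim_gradient_study()].
#' @param min_cov Coverage threshold for motif CpGs.
#' @param k Running-mean window (points).
#' @param thresholds Enrichment class thresholds.
#' @param shift Tag shift, bp.
#' @param pseudo Enrichment pseudocount.
#' @return List: `sites` (enrichment + class per site), `curve` (sorted
#'   points with running mean), `spearman` (running mean vs enrichment),
#'   `accuracy` (tier recovery when the study carries expected classes).
#' @export
analyze_gradient <- function(study, min_cov = 10, k = 101,
                             thresholds = c(1, 3), shift = 60, pseudo = 8) {
  ip_tags <- shift_and_weight(study$ip, shift, study$genome$sizes)
  ct_tags <- shift_and_weight(study$control, shift, study$genome$sizes)
  centers <- motif_center(study$truth)
  wins <- data.frame(chrom = study$truth$chrom, start = centers - 100L,
                     end = centers + 100L, strand = ".")
  enr <- enrichment(ip_tags, ct_tags, wins, pseudo = pseudo)
  sites <- study$truth
  sites$enrichment <- enr$log2_enrichment
  sites$class <- classify_sites(sites$enrichment, thresholds)

  wg_calls <- extract_methylation(study$wg, study$genome$seqs,
                                  study$genome$cpg)
  cpg_calls <- collapse_strands(wg_calls)
  cpg_calls <- filter_coverage(cpg_calls, min_cov)
  pts <- list()
  for (i in seq_len(nrow(sites))) {
    offs <- sites$cpg_offsets[[i]]
    if (!length(offs)) next
    pos <- sites$start[i] + offs
    m <- cpg_calls[cpg_calls$chrom == sites$chrom[i] & cpg_calls$pos %in% pos, ]
    if (!nrow(m)) next
    pts[[length(pts) + 1]] <- data.frame(
      site = i, enrichment = sites$enrichment[i], meth_pct = m$meth_pct,
      occupancy = sites$occupancy[i], stringsAsFactors = FALSE
    )
  }
  points <- do.call(rbind, pts)
  curve <- motif_cpg_curve(points, k)
  spearman <- stats::cor(curve$run_mean, curve$enrichment, method = "spearman")
  accuracy <- if (!is.null(study$truth$expected_class))
    mean(as.character(sites$class) == study$truth$expected_class)
  else NA_real_
  list(sites = sites, curve = curve, spearman = spearman, accuracy = accuracy)
}

#' Simulate a 5hmC turnover study
#'
#' A toy genome carrying NP-specific, ES-specific and constitutive LMRs plus
#' UMRs (the unsegmented remainder is FMR). hMeDIP libraries for two cell
#' states x two biological replicates place 5hmC signal on the state's
#' specific LMRs (and, in both states, on constitutive LMRs) over a uniform
#' background, with multi-mapping decoys. Bisulfite libraries for both
#' states plant reciprocal methylation turnover: LMRs gaining 5hmC in NP
#' lose methylation (60% to 20%) and vice versa, while constitutive LMRs
#' stay at 30%.
#'
#' @param n_np,n_es Numbers of NP-/ES-specific LMRs (5 kb each).
#' @param n_const Constitutive LMRs (2 kb each).
#' @param n_umr UMRs (1 kb each).
#' @param chrom_len,n_chrom Genome dimensions (default 2 x 2.5 Mb).
#' @param lmr_amp,const_amp Per-base 5hmC signal weight at specific and
#'   constitutive LMRs, relative to background weight 1 (the specific-LMR
#'   default of 40 reflects the strong overrepresentation of state-specific
#'   5hmC at matching LMRs).
#' @param ip_reads Reads per hMeDIP library.
#' @param meth_depth Bisulfite coverage of LMR centers.
#' @param seed Integer seed.
#' @return List: `genome`, `segments` (with FMR complement), `hmedip`
#'   (alignments per `es1`/`es2`/`np1`/`np2`), `wgbs` (per `es`/`np`),
#'   `lmr_regions` (central 1 kb windows used for methylation), design
#'   parameters.
#' @export
sim_turnover_study <- function(n_np = 20, n_es = 20, n_const = 40,
                               n_umr = 20, chrom_len = 2500000, n_chrom = 2,
                               lmr_amp = 40, const_amp = 20,
                               ip_reads = 100000, meth_depth = 15, seed = 1) {
  lmr_len <- 5000L
  const_len <- 2000L
  umr_len <- 1000L
  base <- make_genome(n_chrom = n_chrom, chrom_len = chrom_len, gc = 0.42,
                      seed = derive_seed(seed, 1))
  sizes <- base$sizes
  # slot-based placement keeps segments >= 6 kb apart
  widths <- c(rep(lmr_len, n_np + n_es), rep(const_len, n_const),
              rep(umr_len, n_umr))
  classes <- c(rep("LMR", n_np + n_es + n_const), rep("UMR", n_umr))
  specs <- c(rep("NP_specific", n_np), rep("ES_specific", n_es),
             rep("constitutive", n_const + n_umr))
  slot <- max(widths) + 6000L
  n_slots <- sum(sizes %/% slot)
  if (n_slots < length(widths))
    stop("sim_turnover_study: genome too small for segment layout")
  segments <- with_seed(derive_seed(seed, 2), {
    slots <- unlist(lapply(names(sizes), function(ch)
      paste(ch, seq_len(sizes[[ch]] %/% slot) - 1L)), use.names = FALSE)
    pick <- sample(slots, length(widths))
    parts <- strsplit(pick, " ")
    # jitter within the slot so segment edges are not phase-locked to the
    # differential-window tiling
    data.frame(
      chrom = vapply(parts, `[`, "", 1),
      start = as.integer(vapply(parts, `[`, "", 2)) * slot + 1500L +
        sample.int(2000L, length(widths), replace = TRUE),
      stringsAsFactors = FALSE
    )
  })
  segments$end <- segments$start + as.integer(widths)
  segments$name <- sprintf("seg%03d", seq_len(nrow(segments)))
  segments$score <- 0
  segments$strand <- "."
  segments$seg_class <- classes
  segments$specificity <- specs
  # FMR complement
  fmr <- do.call(rbind, lapply(names(sizes), function(ch) {
    covered <- reduce_intervals(segments[segments$chrom == ch, ])
    gaps <- IRanges::gaps(IRanges::IRanges(covered$start + 1L, covered$end),
                          start = 1L, end = sizes[[ch]])
    data.frame(chrom = ch, start = IRanges::start(gaps) - 1L,
               end = IRanges::end(gaps), stringsAsFactors = FALSE)
  }))
  fmr <- fmr[fmr$end > fmr$start, ]
  fmr$name <- sprintf("fmr%03d", seq_len(nrow(fmr)))
  fmr$score <- 0
  fmr$strand <- "."
  fmr$seg_class <- "FMR"
  fmr$specificity <- "NA"
  segments <- rbind(segments, fmr)
  segments <- segments[order(segments$chrom, segments$start), ]
  rownames(segments) <- NULL

  sig_for <- function(state) {
    sel <- segments$seg_class == "LMR" &
      segments$specificity %in% c(paste0(state, "_specific"), "constitutive")
    s <- segments[sel, c("chrom", "start", "end", "specificity")]
    s$weight <- ifelse(s$specificity == "constitutive", const_amp, lmr_amp)
    s
  }
  hmedip <- list(
    es1 = simulate_ip_reads(sizes, sig_for("ES"), ip_reads, sample_id = "es1",
                            seed = derive_seed(seed, 11)),
    es2 = simulate_ip_reads(sizes, sig_for("ES"), ip_reads, sample_id = "es2",
                            seed = derive_seed(seed, 12)),
    np1 = simulate_ip_reads(sizes, sig_for("NP"), ip_reads, sample_id = "np1",
                            seed = derive_seed(seed, 13)),
    np2 = simulate_ip_reads(sizes, sig_for("NP"), ip_reads, sample_id = "np2",
                            seed = derive_seed(seed, 14))
  )

  lmrs <- segments[segments$seg_class == "LMR", ]
  mid <- (lmrs$start + lmrs$end) %/% 2L
  lmr_regions <- data.frame(chrom = lmrs$chrom, start = mid - 500L,
                            end = mid + 500L, specificity = lmrs$specificity,
                            name = lmrs$name, stringsAsFactors = FALSE)
  meth_level <- function(state) {
    ifelse(lmr_regions$specificity == "constitutive", 0.30,
           ifelse(lmr_regions$specificity == paste0(state, "_specific"),
                  0.20, 0.60))
  }
  genome <- base[c("seqs", "sizes", "cpg")]
  states <- c(es = "ES", np = "NP")
  wgbs <- lapply(seq_along(states), function(si) {
    state <- states[[si]]
    cfg <- scenario_config("unlinked", occupancy = 0.5,
                           demeth = 1 - meth_level(state),
                           seed = derive_seed(seed, 20 + si))
    mols <- simulate_molecules(lmr_regions, genome, cfg, n_molecules = 200,
                               region_width = 1000)
    simulate_bisulfite_reads(genome, mols, read_len = 50, depth = meth_depth,
                             conversion_rate = 0.99, mode = "wg",
                             sample_id = paste0("wgbs_", state),
                             seed = derive_seed(seed, 30 + si))
  })
  names(wgbs) <- names(states)
  list(genome = genome, segments = segments, hmedip = hmedip, wgbs = wgbs,
       lmr_regions = lmr_regions, lmr_amp = lmr_amp, const_amp = const_amp)
}

#' Differential 5hmC windows, segment enrichment and turnover correlation
#'
#' The downstream half of the turnover analysis: shifts and weights the
#' hMeDIP alignments, computes per-replicate sliding-window fold changes,
#' flags windows passing the dual-replicate rule, merges them into gain and
#' loss regions, cross-tabulates observed/expected base enrichment in
#' segment types, measures base-level recovery against the planted
#' NP-specific LMRs, and correlates per-LMR 5hmC change with methylation
#' change.
#'
#' @param study Output of [sim_turnover_study()].
#' @param params [fc_params()].
#' @param shift Tag shift, bp.
#' @param min_cov Coverage filter for per-LMR methylation.
#' @return List: `windows` (flagged tiling), `regions`, `folds`,
#'   `sensitivity`, `fp_rate`, `turnover` (per-LMR change table),
#'   `turnover_r`, `fraction_at_lmr`.
#' @export
analyze_turnover <- function(study, params = fc_params(), shift = 60,
                             min_cov = 5) {
  sizes <- study$genome$sizes
  tg <- lapply(study$hmedip, shift_and_weight, shift = shift, sizes = sizes)
  ws1 <- window_scan(tg$es1, tg$np1, sizes, params)
  ws2 <- window_scan(tg$es2, tg$np2, sizes, params)
  flagged <- consistent_windows(ws1, ws2, params$threshold)
  regions <- merge_regions(flagged)
  segs <- study$segments
  genome_size <- sum(sizes)
  folds <- fold_table(list(gain_NP = regions$gain, loss_NP = regions$loss),
                      segs, genome_size)
  np_lmr <- segs[segs$seg_class == "LMR" & segs$specificity == "NP_specific", ]
  planted <- sum(interval_width(np_lmr))
  obs <- observed_overlap(regions$gain, np_lmr)
  gain_bases <- sum(interval_width(regions$gain))
  sensitivity <- if (planted > 0) obs / planted else NA_real_
  fp_rate <- (gain_bases - obs) / (genome_size - planted)

  calls <- lapply(study$wgbs, function(a)
    extract_methylation(a, study$genome$seqs, study$genome$cpg))
  calls <- lapply(calls, filter_coverage, min_cov = min_cov)
  lr <- study$lmr_regions
  centers <- data.frame(chrom = lr$chrom,
                        center = (lr$start + lr$end) %/% 2L)
  meth_es <- window_methylation(calls$es, centers, width = 1000)
  meth_np <- window_methylation(calls$np, centers, width = 1000)
  pooled_fc <- (flagged$log2fc_rep1 + flagged$log2fc_rep2) / 2
  ov <- overlap_pairs(flagged[c("chrom", "start", "end")],
                      lr[c("chrom", "start", "end")])
  d5hmc <- rep(NA_real_, nrow(lr))
  for (i in unique(ov$subject))
    d5hmc[i] <- mean(pooled_fc[ov$query[ov$subject == i]])
  turnover <- data.frame(lr, d5hmc = d5hmc, dmeth = meth_np - meth_es)
  ok <- stats::complete.cases(turnover[c("d5hmc", "dmeth")])
  turnover_r <- change_correlation(turnover$d5hmc[ok], turnover$dmeth[ok])
  all_lmr <- segs[segs$seg_class == "LMR", ]
  change_regions <- rbind(regions$gain, regions$loss)
  fraction_at_lmr <- if (nrow(change_regions))
    fraction_in_segments(change_regions, all_lmr) else NA_real_
  list(windows = flagged, regions = regions, folds = folds,
       sensitivity = sensitivity, fp_rate = fp_rate, turnover = turnover,
       turnover_r = turnover_r, fraction_at_lmr = fraction_at_lmr)
}
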