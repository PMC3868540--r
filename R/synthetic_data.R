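#' Scenario configuration for occupancy-coupled methylation
#'
#' Describes how transcription-factor binding and per-molecule CpG
#' methylation are linked at simulated sites. In the `static` scenario
#' binding is deterministically coupled to the methylation state: bound
#' molecules are unmethylated at site-proximal CpGs and unbound molecules
#' fully methylated, so the population methylation equals
#' `1 - occupancy`. In the `unlinked` scenario the methylation state is
#' drawn independently of binding with marginal demethylation probability
#' `demeth`, so bound molecules display the same methylation variation as
#' the whole population.
#'
#' @param scenario `"static"` or `"unlinked"`.
#' @param occupancy Per-site probability that a molecule is bound (scalar or
#'   one value per site).
#' @param demeth Marginal probability of the unmethylated state (`unlinked`
#'   scenario). Ignored for `static`.
#' @param demeth_bound,demeth_unbound Explicit conditional demethylation
#'   probabilities; default to the scenario presets.
#' @param hmc_prob Probability that a methylated CpG carries 5hmC instead of
#'   5mC (state `H`; protected from bisulfite conversion like 5mC).
#' @param seed Integer seed.
#' @return List of class `scenario_config`.
#' @export
scenario_config <- function(scenario = c("static", "unlinked"),
                            occupancy = 0.7, demeth = 0.7,
                            demeth_bound = NULL, demeth_unbound = NULL,
                            hmc_prob = 0, seed = 1) {
  scenario <- match.arg(scenario)
  if (is.null(demeth_bound))
    demeth_bound <- if (scenario == "static") 1 else demeth
  if (is.null(demeth_unbound))
    demeth_unbound <- if (scenario == "static") 0 else demeth
  probs <- c(occupancy, demeth_bound, demeth_unbound, hmc_prob)
  if (any(probs < 0 | probs > 1))
    stop("scenario_config: probabilities must be in [0, 1]")
  structure(list(scenario = scenario, occupancy = occupancy,
                 demeth_bound = demeth_bound, demeth_unbound = demeth_unbound,
                 hmc_prob = hmc_prob, seed = as.integer(seed)),
            class = "scenario_config")
}

#' Generate a random toy genome
#'
#' Bases are drawn i.i.d. with the given GC content. Optional CpG islands
#' are rewritten dinucleotide-wise with an elevated CG rate to emulate
#' CpG-dense unmethylated regions. Deterministic under `seed`.
#'
#' @param n_chrom Number of chromosomes.
#' @param chrom_len Length of each chromosome in bp (>= 10 kb recommended;
#'   shorter lengths are allowed for unit fixtures).
#' @param gc GC content in (0, 1); the limits 0 and 1 are permitted for
#'   degenerate fixtures.
#' @param cpg_islands Optional interval `data.frame` of islands to enrich.
#' @param island_cpg_rate Per-dinucleotide probability of emitting `CG`
#'   inside islands.
#' @param seed Integer seed.
#' @return List: `seqs` (named character vector), `sizes`, `cpg`
#'   (CpG coordinate table).
#' @export
make_genome <- function(n_chrom = 2, chrom_len = 50000, gc = 0.42,
                        cpg_islands = NULL, island_cpg_rate = 0.15, seed = 1) {
  if (gc < 0 || gc > 1) stop("make_genome: gc must be in [0, 1]")
  if (n_chrom < 1 || chrom_len < 1) stop("make_genome: bad dimensions")
  probs <- c((1 - gc) / 2, gc / 2, gc / 2, (1 - gc) / 2)
  seqs <- with_seed(seed, {
    out <- vapply(seq_len(n_chrom), function(i) {
      paste(sample(BASES, chrom_len, replace = TRUE, prob = probs),
            collapse = "")
    }, "")
    names(out) <- paste0("chr", seq_len(n_chrom))
    if (!is.null(cpg_islands)) {
      for (k in seq_len(nrow(cpg_islands))) {
        ch <- cpg_islands$chrom[k]
        w <- cpg_islands$end[k] - cpg_islands$start[k]
        ndi <- w %/% 2L
        di <- ifelse(stats::runif(ndi) < island_cpg_rate, "CG",
                     paste0(sample(BASES, ndi, TRUE, prob = probs),
                            sample(BASES, ndi, TRUE, prob = probs)))
        repl <- substr(paste(di, collapse = ""), 1, w)
        substr(out[[ch]], cpg_islands$start[k] + 1L, cpg_islands$end[k]) <- repl
      }
    }
    out
  })
  list(seqs = seqs, sizes = seq_sizes(seqs), cpg = cpg_table(seqs))
}

#' Plant motif instances into a genome
#'
#' Overwrites the genome at chosen loci with sequences drawn from (or the
#' consensus of) a PWM, optionally inserting a variable-length random linker
#' after a fixed motif position (gapped motifs). Returns both the edited
#' genome and a ground-truth table of the planted sites.
#'
#' @param genome Genome list from [make_genome()] (or a named character
#'   vector of sequences).
#' @param p A `pwm` object.
#' @param sites Either an interval-less `data.frame` with `chrom` and
#'   `start` columns giving planting positions, or an integer count of sites
#'   to place at random non-overlapping positions.
#' @param mode `"sample"` (draw letters from the PWM) or `"consensus"`.
#' @param linker_range Integer linker lengths for gapped motifs, or `NULL`.
#' @param linker_after Motif position (1-based) after which the linker is
#'   inserted.
#' @param min_spacing Minimum distance between random placements.
#' @param seed Integer seed.
#' @return List: `seqs` (edited genome), `sizes`, `cpg` (recomputed), and
#'   `truth` — a hit-like `data.frame` with `chrom`, `start`, `end`,
#'   `strand`, `linker_len`, `seq`, `score` and `cpg_offsets`.
#' @export
plant_motifs <- function(genome, p, sites, mode = c("sample", "consensus"),
                         linker_range = NULL, linker_after = NULL,
                         min_spacing = 500, seed = 1) {
  mode <- match.arg(mode)
  seqs <- if (is.list(genome) && !is.null(genome$seqs)) genome$seqs else genome
  sizes <- seq_sizes(seqs)
  gapped <- !is.null(linker_range)
  with_seed(seed, {
    if (is.numeric(sites) && length(sites) == 1) {
      n <- as.integer(sites)
      maxw <- p$length + if (gapped) max(linker_range) else 0L
      placed <- list()
      for (ch in names(seqs)) placed[[ch]] <- integer(0)
      sites_df <- data.frame(chrom = character(0), start = integer(0))
      tries <- 0L
      while (nrow(sites_df) < n && tries < n * 200L) {
        tries <- tries + 1L
        ch <- sample(names(seqs), 1, prob = sizes / sum(sizes))
        st <- sample.int(sizes[[ch]] - maxw, 1) - 1L
        if (!any(abs(placed[[ch]] - st) < maxw + min_spacing)) {
          placed[[ch]] <- c(placed[[ch]], st)
          sites_df <- rbind(sites_df, data.frame(chrom = ch, start = st))
        }
      }
      if (nrow(sites_df) < n)
        stop("plant_motifs: could not place ", n, " non-overlapping sites")
      sites <- sites_df
    }
    truth <- vector("list", nrow(sites))
    for (i in seq_len(nrow(sites))) {
      l <- if (gapped) sample(rep(linker_range, 2), 1) else 0L
      width <- p$length + l
      ch <- sites$chrom[i]
      st <- sites$start[i]
      if (st < 0 || st + width > sizes[[ch]])
        stop("plant_motifs: site beyond chromosome end")
      letters_at <- function(row) {
        if (mode == "consensus") colnames(p$matrix)[which.max(p$matrix[row, ])]
        else sample(BASES, 1, prob = p$matrix[row, ])
      }
      core <- vapply(seq_len(p$length), letters_at, "")
      linker <- if (l > 0) sample(BASES, l, TRUE) else character(0)
      planted <- paste(c(core[seq_len(if (gapped) linker_after else p$length)],
                         linker,
                         if (gapped) core[(linker_after + 1):p$length]),
                       collapse = "")
      substr(seqs[[ch]], st + 1L, st + width) <- planted
      truth[[i]] <- data.frame(
        chrom = ch, start = st, end = st + width, strand = "+",
        linker_len = as.integer(l), seq = planted,
        score = score_window(p, paste(core, collapse = "")),
        stringsAsFactors = FALSE
      )
    }
    truth <- do.call(rbind, truth)
    truth <- truth[order(truth$chrom, truth$start), ]
    rownames(truth) <- NULL
    truth <- annotate_cpg(truth, seqs)
    list(seqs = seqs, sizes = sizes, cpg = cpg_table(seqs), truth = truth)
  })
}

#' Simulate per-molecule methylation states at sites
#'
#' For each site, draws `n_molecules` DNA molecules covering the
#' `region_width` bp window around the site center. Each molecule is bound
#' with probability `occupancy` and adopts a molecule-level methylation
#' state: unmethylated (`U`) with the scenario's conditional probability
#' given its binding state, otherwise methylated, with methylated CpGs
#' switched to hydroxymethylated (`H`) with probability `hmc_prob`.
#' Methylation is symmetric on the two strands of a CpG.
#'
#' @param truth Planted-site table from [plant_motifs()] (or any hit-like
#'   `data.frame`).
#' @param genome Genome list (edited, from [plant_motifs()]).
#' @param config A [scenario_config()].
#' @param n_molecules Molecules per site.
#' @param region_width Width of the simulated region around each site
#'   center.
#' @return List of class `molecule_sim`; one element per site with fields
#'   `chrom`, `region_start`, `region_end`, `cpg_pos`, `bound` (logical) and
#'   `meth` (molecules x CpGs character matrix of `M`/`U`/`H`).
#' @export
simulate_molecules <- function(truth, genome, config, n_molecules = 200,
                               region_width = 200) {
  stopifnot(inherits(config, "scenario_config"), n_molecules >= 1)
  centers <- motif_center(truth)
  occ <- rep_len(config$occupancy, nrow(truth))
  db <- rep_len(config$demeth_bound, nrow(truth))
  du <- rep_len(config$demeth_unbound, nrow(truth))
  cpg_by_chrom <- lapply(split(genome$cpg$pos, genome$cpg$chrom), sort)
  out <- with_seed(config$seed, {
    lapply(seq_len(nrow(truth)), function(i) {
      ch <- truth$chrom[i]
      rs <- max(0L, centers[i] - region_width %/% 2L)
      re <- min(genome$sizes[[ch]], centers[i] + region_width %/% 2L)
      P <- cpg_by_chrom[[ch]]
      cp <- if (is.null(P)) integer(0) else
        P[P >= rs & P < re - 1L]  # need the G inside the region too
      bound <- stats::runif(n_molecules) < occ[i]
      pU <- ifelse(bound, db[i], du[i])
      unmeth <- stats::runif(n_molecules) < pU
      meth <- matrix(ifelse(unmeth, "U", "M"), n_molecules, length(cp))
      if (config$hmc_prob > 0 && length(cp)) {
        hm <- meth == "M" &
          matrix(stats::runif(n_molecules * length(cp)) < config$hmc_prob,
                 n_molecules, length(cp))
        meth[hm] <- "H"
      }
      list(chrom = ch, region_start = rs, region_end = re, site_index = i,
           cpg_pos = cp, bound = bound, meth = meth)
    })
  })
  structure(out, class = "molecule_sim", config = config)
}

#' Population methylation per simulated site
#'
#' @param mols A `molecule_sim` object.
#' @return Numeric vector: mean fraction of methylated (M or H) CpG states
#'   per site, in percent (`NA` for sites without CpGs).
#' @export
molecule_methylation <- function(mols) {
  vapply(mols, function(s) {
    if (!length(s$cpg_pos)) return(NA_real_)
    100 * mean(s$meth != "U")
  }, 0)
}

#' Simulate bisulfite-converted reads from molecule populations
#'
#' Whole-genome mode (`mode = "wg"`) samples molecules uniformly; ChIP mode
#' samples bound molecules, contaminated by a non-specific background
#' fraction of molecules drawn from the whole population. Reads are emitted
#' pre-aligned with reference-projected sequences: an unmethylated cytosine
#' is converted (plus-strand reads `C -> T`, minus-strand reads `G -> A` at
#' the guanine position) with probability `conversion_rate`; methylated and
#' hydroxymethylated cytosines resist conversion (bisulfite does not
#' distinguish 5mC from 5hmC). Cytosines outside CpG context are always
#' unmethylated. At sites with no bound molecule, ChIP mode yields only the
#' background read fraction.
#'
#' @param genome Genome list.
#' @param mols A `molecule_sim` object.
#' @param read_len Read length, bp.
#' @param depth Target per-base coverage of each region.
#' @param conversion_rate Bisulfite conversion rate in (0, 1].
#' @param mode `"wg"` or `"chip"`.
#' @param chip_background Fraction of ChIP reads drawn from the total
#'   population instead of the bound fraction (non-specific pulldown).
#' @param sample_id Sample label.
#' @param seed Integer seed.
#' @return Alignment `data.frame` with `seq` column (`n_hits = 1`).
#' @export
simulate_bisulfite_reads <- function(genome, mols, read_len = 50, depth = 50,
                                     conversion_rate = 1,
                                     mode = c("wg", "chip"),
                                     chip_background = 0.02,
                                     sample_id = NULL, seed = 1) {
  mode <- match.arg(mode)
  if (conversion_rate <= 0 || conversion_rate > 1)
    stop("simulate_bisulfite_reads: conversion_rate must be in (0, 1]")
  if (depth <= 0) {
    warning("depth 0: empty read stream")
    return(cbind(empty_alignments(sample_id %||% mode), seq = character(0)))
  }
  if (is.null(sample_id)) sample_id <- mode
  recs <- with_seed(seed, {
    lapply(seq_along(mols), function(si) {
      s <- mols[[si]]
      L <- s$region_end - s$region_start
      if (L < read_len) return(NULL)
      n_reads <- ceiling(depth * L / read_len)
      n_mol <- length(s$bound)
      if (mode == "wg") {
        mol <- sample.int(n_mol, n_reads, replace = TRUE)
      } else {
        bnd <- which(s$bound)
        if (length(bnd)) {
          from_bg <- stats::runif(n_reads) < chip_background
          mol <- integer(n_reads)
          mol[from_bg] <- sample.int(n_mol, sum(from_bg), replace = TRUE)
          if (any(!from_bg))
            mol[!from_bg] <- bnd[sample.int(length(bnd), sum(!from_bg),
                                            replace = TRUE)]
        } else {
          n_reads <- max(0L, round(n_reads * chip_background))
          if (n_reads == 0) return(NULL)
          mol <- sample.int(n_mol, n_reads, replace = TRUE)
        }
      }
      refchars <- strsplit(substr(genome$seqs[[s$chrom]], s$region_start + 1L,
                                  s$region_end), "")[[1]]
      starts <- s$region_start +
        sample.int(L - read_len + 1L, n_reads, replace = TRUE) - 1L
      strands <- sample(c("+", "-"), n_reads, replace = TRUE)
      seqs <- character(n_reads)
      for (r in seq_len(n_reads)) {
        loc <- (starts[r] - s$region_start + 1L):(starts[r] - s$region_start + read_len)
        rd <- refchars[loc]
        gpos <- starts[r] + seq_len(read_len) - 1L  # global 0-based
        st <- s$meth[mol[r], , drop = TRUE]
        if (strands[r] == "+") {
          ci <- which(rd == "C")
          if (length(ci)) {
            j <- match(gpos[ci], s$cpg_pos)
            meth_protected <- !is.na(j) & st[j] != "U"
            conv <- !meth_protected & stats::runif(length(ci)) < conversion_rate
            rd[ci[conv]] <- "T"
          }
        } else {
          gi <- which(rd == "G")
          if (length(gi)) {
            j <- match(gpos[gi] - 1L, s$cpg_pos)
            meth_protected <- !is.na(j) & st[j] != "U"
            conv <- !meth_protected & stats::runif(length(gi)) < conversion_rate
            rd[gi[conv]] <- "A"
          }
        }
        seqs[r] <- paste(rd, collapse = "")
      }
      data.frame(chrom = s$chrom, start = starts, end = starts + read_len,
                 strand = strands,
                 read_id = sprintf("%s_s%03d_r%05d", sample_id, si,
                                   seq_len(n_reads)),
                 n_hits = 1L, sample = sample_id, seq = seqs,
                 stringsAsFactors = FALSE)
    })
  })
  recs <- recs[!vapply(recs, is.null, TRUE)]
  if (!length(recs))
    return(cbind(empty_alignments(sample_id), seq = character(0)))
  out <- do.call(rbind, recs)
  rownames(out) <- NULL
  out
}

#' Simulate immunoprecipitation reads from a signal track
#'
#' Fragment centers are drawn from a mixture of a uniform genomic background
#' (fraction `background_frac` of the library) and the piecewise-constant
#' signal track (probability proportional to `weight x width` per interval).
#' Each fragment yields one read whose shifted 5' tag (shift = half the
#' fragment length) recovers the fragment center. A configured fraction of
#' reads is made multi-mapping by adding decoy placements at random genomic
#' positions, all sharing the read id with `n_hits` set to the number of
#' placements.
#'
#' @param sizes Named chromosome sizes.
#' @param signal Interval `data.frame` with a `weight` column (relative
#'   per-base sampling weight), or `NULL` for background only.
#' @param n_reads Number of distinct reads (library size).
#' @param read_len Read length, bp.
#' @param frag_len Fragment length, bp (default 120; tags are shifted by
#'   `frag_len / 2`).
#' @param background_frac Fraction of the library sampled uniformly.
#' @param multihit_frac Fraction of reads given decoy placements.
#' @param multihit_max Maximum number of placements per multi-mapping read.
#' @param sample_id Sample label.
#' @param seed Integer seed.
#' @return Alignment `data.frame` (no sequences).
#' @export
simulate_ip_reads <- function(sizes, signal = NULL, n_reads = 100000,
                              read_len = 36, frag_len = 120,
                              background_frac = 0.1, multihit_frac = 0.05,
                              multihit_max = 4, sample_id = "ip", seed = 1) {
  sizes <- vapply(sizes, as.integer, 0L)
  sig_mass <- if (is.null(signal) || nrow(signal) == 0) 0 else
    sum(signal$weight * (signal$end - signal$start))
  if (sig_mass <= 0 && background_frac <= 0)
    stop("simulate_ip_reads: all-zero signal with zero background")
  shift <- frag_len %/% 2L
  with_seed(seed, {
    n_bg <- if (sig_mass <= 0) n_reads else round(n_reads * background_frac)
    n_sig <- n_reads - n_bg
    chrom <- character(n_reads)
    center <- integer(n_reads)
    if (n_bg > 0) {
      ch <- sample(names(sizes), n_bg, replace = TRUE, prob = sizes / sum(sizes))
      chrom[seq_len(n_bg)] <- ch
      center[seq_len(n_bg)] <- floor(stats::runif(n_bg) * sizes[ch])
    }
    if (n_sig > 0) {
      w <- signal$weight * (signal$end - signal$start)
      j <- sample.int(nrow(signal), n_sig, replace = TRUE, prob = w)
      chrom[n_bg + seq_len(n_sig)] <- signal$chrom[j]
      center[n_bg + seq_len(n_sig)] <-
        signal$start[j] + floor(stats::runif(n_sig) * (signal$end[j] - signal$start[j]))
    }
    strand <- sample(c("+", "-"), n_reads, replace = TRUE)
    start <- ifelse(strand == "+", center - shift,
                    center + shift + 1L - read_len)
    start <- pmin(pmax(start, 0L), sizes[chrom] - read_len)
    df <- data.frame(chrom = chrom, start = as.integer(start),
                     end = as.integer(start + read_len), strand = strand,
                     read_id = sprintf("%s_r%06d", sample_id, seq_len(n_reads)),
                     n_hits = 1L, sample = sample_id, stringsAsFactors = FALSE)
    if (multihit_frac > 0) {
      nm <- round(n_reads * multihit_frac)
      if (nm > 0) {
        idx <- sample.int(n_reads, nm)
        k <- sample(2:multihit_max, nm, replace = TRUE)
        df$n_hits[idx] <- k
        extra <- data.frame(
          chrom = sample(names(sizes), sum(k - 1), replace = TRUE,
                         prob = sizes / sum(sizes)),
          start = 0L, end = 0L,
          strand = sample(c("+", "-"), sum(k - 1), replace = TRUE),
          read_id = rep(df$read_id[idx], k - 1),
          n_hits = rep(k, k - 1), sample = sample_id,
          stringsAsFactors = FALSE
        )
        extra$start <- as.integer(floor(stats::runif(nrow(extra)) *
                                          (sizes[extra$chrom] - read_len)))
        extra$end <- extra$start + read_len
        df <- rbind(df, extra)
      }
    }
    rownames(df) <- NULL
    df
  })
}
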