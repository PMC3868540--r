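PIPELINE_STAGES <- c("simulate", "methylation", "motifs", "chip",
                     "hmedip-diff", "enrichment", "occupancy", "all")

#' Build a validated run configuration
#'
#' Merges user settings over the defaults. Analysis parameter defaults are
#' the published constants: pseudocount 8, 1 kb windows with 500 bp step,
#' |log2FC| threshold 3, tag shift 60, joint coverage 10x, 200 bp motif
#' windows, 3 kb profile flank.
#'
#' @param config A YAML file path or a nested list.
#' @return List of class `run_config`.
#' @export
run_config <- function(config = list()) {
  if (is.character(config)) {
    if (!file.exists(config)) stop("config file not found: ", config)
    config <- yaml::read_yaml(config)
  }
  defaults <- list(
    experiment = "chipbis",
    scenario = "unlinked",
    seed = 1,
    outdir = "methturnover_run",
    params = list(p = 8, win = 1000, step = 500, threshold = 3, shift = 60,
                  min_cov = 10, window = 200, flank = 3000,
                  scan_threshold = 10, class_thresholds = c(1, 3)),
    sim = list()
  )
  merged <- utils::modifyList(defaults, config)
  if (!merged$experiment %in% c("chipbis", "gradient", "turnover"))
    stop("run_config: unknown experiment '", merged$experiment, "'")
  structure(merged, class = "run_config")
}

stage_manifest <- function(outdir, stage, config, inputs, outputs, counts) {
  manifest <- list(
    stage = stage,
    experiment = config$experiment,
    seed = config$seed,
    params = config$params,
    inputs = as.list(tools::md5sum(inputs[file.exists(inputs)])),
    outputs = as.list(tools::md5sum(outputs[file.exists(outputs)])),
    row_counts = counts
  )
  path <- file.path(outdir, sprintf("manifest_%s.json", stage))
  jsonlite::write_json(manifest, path, auto_unbox = TRUE, pretty = TRUE)
  invisible(path)
}

data_path <- function(config, ...) file.path(config$outdir, "data", ...)
result_path <- function(config, ...) file.path(config$outdir, ...)

#' Run one pipeline stage
#'
#' Configuration-driven driver. Stages: `simulate` (synthetic dataset to
#' disk), `methylation` (per-cytosine calls + bedGraph from bisulfite
#' alignments), `motifs` (PWM scan of the genome), `chip` (enrichment and
#' site classification; gradient experiment), `hmedip-diff` (differential
#' windows and merged regions; turnover experiment), `enrichment`
#' (observed/expected fold table; turnover), `occupancy` (paired
#' ChIP/WG-BisSeq analysis; chipbis), or `all`. Every stage writes a JSON
#' manifest recording parameters, input checksums and row counts, and is
#' byte-reproducible under a fixed seed.
#'
#' @param stage Stage name.
#' @param config A [run_config()], YAML path or list.
#' @return List of produced file paths, invisibly.
#' @export
run_stage <- function(stage, config = list()) {
  if (!stage %in% PIPELINE_STAGES)
    stop("unknown stage '", stage, "'; available: ",
         paste(PIPELINE_STAGES, collapse = ", "))
  config <- run_config(unclass(config))
  if (stage == "all") {
    stages <- switch(config$experiment,
      chipbis = c("simulate", "methylation", "motifs", "occupancy"),
      gradient = c("simulate", "methylation", "motifs", "chip"),
      turnover = c("simulate", "methylation", "hmedip-diff", "enrichment"))
    return(invisible(lapply(stages, run_stage, config = config)))
  }
  dir.create(data_path(config), recursive = TRUE, showWarnings = FALSE)
  switch(stage,
    "simulate" = stage_simulate(config),
    "methylation" = stage_methylation(config),
    "motifs" = stage_motifs(config),
    "chip" = stage_chip(config),
    "hmedip-diff" = stage_hmedip(config),
    "enrichment" = stage_enrichment(config),
    "occupancy" = stage_occupancy(config)
  )
}

stage_simulate <- function(config) {
  ex <- config$experiment
  out <- character(0)
  if (ex == "chipbis") {
    study <- do.call(sim_chipbis_study,
                     c(list(scenario = config$scenario, seed = config$seed),
                       config$sim))
    write_fasta(study$genome$seqs, data_path(config, "genome.fa"))
    write_segments(study$segments, data_path(config, "segments.bed"))
    write_pwm(example_pwm("ctcf_like"), data_path(config, "motif.pwm"))
    write_tsv(study$truth, data_path(config, "truth.tsv"))
    write_sam(study$wg, study$genome$sizes, data_path(config, "wg.sam"))
    write_sam(study$chip, study$genome$sizes, data_path(config, "chip.sam"))
    if (nrow(study$dmrs))
      write_tsv(study$dmrs, data_path(config, "dmrs.tsv"))
    out <- data_path(config, c("genome.fa", "segments.bed", "motif.pwm",
                               "truth.tsv", "wg.sam", "chip.sam"))
  } else if (ex == "gradient") {
    study <- do.call(sim_gradient_study,
                     c(list(seed = config$seed), config$sim))
    write_fasta(study$genome$seqs, data_path(config, "genome.fa"))
    write_pwm(example_pwm("ctcf_like"), data_path(config, "motif.pwm"))
    write_tsv(study$truth, data_path(config, "truth.tsv"))
    write_sam(study$wg, study$genome$sizes, data_path(config, "wg.sam"))
    write_alignments_tsv(study$ip, data_path(config, "ip.tsv"))
    write_alignments_tsv(study$control, data_path(config, "input.tsv"))
    out <- data_path(config, c("genome.fa", "motif.pwm", "truth.tsv",
                               "wg.sam", "ip.tsv", "input.tsv"))
  } else {
    study <- do.call(sim_turnover_study,
                     c(list(seed = config$seed), config$sim))
    write_fasta(study$genome$seqs, data_path(config, "genome.fa"))
    write_segments(study$segments, data_path(config, "segments.bed"))
    for (nm in names(study$hmedip))
      write_alignments_tsv(study$hmedip[[nm]],
                           data_path(config, sprintf("hmedip_%s.tsv", nm)))
    for (nm in names(study$wgbs))
      write_sam(study$wgbs[[nm]], study$genome$sizes,
                data_path(config, sprintf("wgbs_%s.sam", nm)))
    write_tsv(study$lmr_regions, data_path(config, "lmr_regions.tsv"))
    out <- data_path(config, c("genome.fa", "segments.bed",
                               sprintf("hmedip_%s.tsv", names(study$hmedip)),
                               sprintf("wgbs_%s.sam", names(study$wgbs))))
  }
  stage_manifest(config$outdir, "simulate", config, character(0), out,
                 list(files = length(out)))
  invisible(out)
}

bisulfite_inputs <- function(config) {
  pats <- c(chipbis = "^(wg|chip)\\.sam$", gradient = "^wg\\.sam$",
            turnover = "^wgbs_.*\\.sam$")
  list.files(data_path(config), pats[[config$experiment]], full.names = TRUE)
}

stage_methylation <- function(config) {
  genome <- read_fasta(data_path(config, "genome.fa"))
  cpg <- cpg_table(genome)
  ins <- bisulfite_inputs(config)
  if (!length(ins)) stop("methylation stage: no bisulfite alignments; run 'simulate' first")
  outs <- character(0)
  counts <- list()
  for (f in ins) {
    sample <- sub("\\.sam$", "", basename(f))
    aln <- read_alignments(f, sample = sample)
    calls <- extract_methylation(aln, genome, cpg)
    tsv <- result_path(config, sprintf("calls_%s.tsv", sample))
    bg <- result_path(config, sprintf("calls_%s.bedGraph", sample))
    write_tsv(calls, tsv)
    write_bedgraph(calls, bg)
    outs <- c(outs, tsv, bg)
    counts[[sample]] <- nrow(calls)
  }
  stage_manifest(config$outdir, "methylation", config, ins, outs, counts)
  invisible(outs)
}

stage_motifs <- function(config) {
  genome <- read_fasta(data_path(config, "genome.fa"))
  p <- read_pwm(data_path(config, "motif.pwm"))
  hits <- scan_pwm(p, genome, threshold = config$params$scan_threshold)
  hits <- annotate_cpg(hits, genome)
  out <- result_path(config, "motif_hits.tsv")
  write_tsv(hits, out)
  stage_manifest(config$outdir, "motifs", config,
                 data_path(config, c("genome.fa", "motif.pwm")), out,
                 list(hits = nrow(hits)))
  invisible(out)
}

stage_chip <- function(config) {
  if (config$experiment != "gradient")
    stop("chip stage applies to the gradient experiment")
  genome <- read_fasta(data_path(config, "genome.fa"))
  sizes <- seq_sizes(genome)
  ip <- read_alignments(data_path(config, "ip.tsv"), "ip")
  ct <- read_alignments(data_path(config, "input.tsv"), "input")
  truth <- utils::read.delim(data_path(config, "truth.tsv"))
  centers <- motif_center(truth)
  wins <- data.frame(chrom = truth$chrom, start = centers - 100L,
                     end = centers + 100L, strand = ".")
  enr <- enrichment(shift_and_weight(ip, config$params$shift, sizes),
                    shift_and_weight(ct, config$params$shift, sizes),
                    wins, pseudo = config$params$p)
  enr$class <- as.character(
    classify_sites(enr$log2_enrichment, config$params$class_thresholds))
  out <- result_path(config, "site_enrichment.tsv")
  write_tsv(enr, out)
  stage_manifest(config$outdir, "chip", config,
                 data_path(config, c("ip.tsv", "input.tsv")), out,
                 list(sites = nrow(enr)))
  invisible(out)
}

stage_hmedip <- function(config) {
  if (config$experiment != "turnover")
    stop("hmedip-diff stage applies to the turnover experiment")
  genome <- read_fasta(data_path(config, "genome.fa"))
  sizes <- seq_sizes(genome)
  pr <- fc_params(config$params$p, config$params$win, config$params$step,
                  config$params$threshold)
  tags <- lapply(c("es1", "es2", "np1", "np2"), function(nm)
    shift_and_weight(read_alignments(
      data_path(config, sprintf("hmedip_%s.tsv", nm)), nm),
      config$params$shift, sizes))
  names(tags) <- c("es1", "es2", "np1", "np2")
  flagged <- consistent_windows(
    window_scan(tags$es1, tags$np1, sizes, pr),
    window_scan(tags$es2, tags$np2, sizes, pr), pr$threshold)
  regions <- merge_regions(flagged)
  outs <- c(result_path(config, "hmedip_windows.tsv"),
            result_path(config, "gain_NP.bed"),
            result_path(config, "loss_NP.bed"))
  write_tsv(flagged, outs[1])
  for (i in 1:2) {
    r <- regions[[c("gain", "loss")[i]]]
    writeLines(sprintf("%s\t%d\t%d", r$chrom, r$start, r$end), outs[i + 1])
  }
  stage_manifest(config$outdir, "hmedip-diff", config,
                 data_path(config, sprintf("hmedip_%s.tsv", names(tags))),
                 outs, list(windows = nrow(flagged),
                            gain = nrow(regions$gain),
                            loss = nrow(regions$loss)))
  invisible(outs)
}

read_bed3 <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  if (!length(lines))
    return(data.frame(chrom = character(0), start = integer(0), end = integer(0)))
  f <- strsplit(lines, "\t")
  data.frame(chrom = vapply(f, `[`, "", 1),
             start = as.integer(vapply(f, `[`, "", 2)),
             end = as.integer(vapply(f, `[`, "", 3)), stringsAsFactors = FALSE)
}

stage_enrichment <- function(config) {
  if (config$experiment != "turnover")
    stop("enrichment stage applies to the turnover experiment")
  genome <- read_fasta(data_path(config, "genome.fa"))
  segments <- read_segments(data_path(config, "segments.bed"))
  regions <- list(gain_NP = read_bed3(result_path(config, "gain_NP.bed")),
                  loss_NP = read_bed3(result_path(config, "loss_NP.bed")))
  folds <- fold_table(regions, segments, sum(seq_sizes(genome)))
  out <- result_path(config, "fold_enrichment.tsv")
  write_tsv(folds, out)
  stage_manifest(config$outdir, "enrichment", config,
                 c(result_path(config, c("gain_NP.bed", "loss_NP.bed")),
                   data_path(config, "segments.bed")),
                 out, list(rows = nrow(folds)))
  invisible(out)
}

stage_occupancy <- function(config) {
  if (config$experiment != "chipbis")
    stop("occupancy stage applies to the chipbis experiment")
  genome <- read_fasta(data_path(config, "genome.fa"))
  cpg <- cpg_table(genome)
  wg <- extract_methylation(read_alignments(data_path(config, "wg.sam"), "wg"),
                            genome, cpg)
  chip <- extract_methylation(
    read_alignments(data_path(config, "chip.sam"), "chip"), genome, cpg)
  truth <- utils::read.delim(data_path(config, "truth.tsv"))
  pairs <- paired_table(wg, chip, truth, unit = "window200",
                        min_cov = config$params$min_cov,
                        width = config$params$window)
  dev <- mean_deviation(pairs)
  outs <- c(result_path(config, "paired_methylation.tsv"),
            result_path(config, "occupancy_summary.json"))
  write_tsv(pairs, outs[1])
  jsonlite::write_json(dev, outs[2], auto_unbox = TRUE, pretty = TRUE,
                       digits = NA)
  stage_manifest(config$outdir, "occupancy", config,
                 data_path(config, c("wg.sam", "chip.sam", "truth.tsv")),
                 outs, list(pairs = nrow(pairs)))
  invisible(outs)
}
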