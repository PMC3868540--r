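---
title: "Occupancy-linked methylation turnover at LMRs: models, parameters and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Occupancy-linked methylation turnover at LMRs}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(methturnover)
```

## The scientific question

Low Methylated Regions (LMRs) are CpG-poor distal regulatory elements with
~30% average methylation, bound by transcription factors (TFs). An average
of 30% is ambiguous at the molecule level. Under a **static** model, 70% of
molecules are fully methylated and never bound while 30% are unmethylated
and bound — occupancy and methylation are two sides of one coin. Under an
**unlinked** model the TF binds regardless of methylation state, bound
molecules mirror the population, and the intermediate average reflects
continuous turnover: methylation is actively removed (through
5-hydroxymethylcytosine, 5hmC) and re-deposited.

The two models make sharply different predictions for an experiment that
sequences *only the bound molecules*: immunoprecipitate TF-bound chromatin,
bisulfite-convert the pulled-down DNA and sequence it (ChIP-BisSeq), then
compare with whole-genome bisulfite sequencing (WG-BisSeq) of the same
cells. This package implements that comparison, the motif-resolved version
of it, the differential 5hmC analysis between cell states, and a synthetic
data generator that plants each scenario so the pipeline can be validated
against known truth.

## Coordinate and data model

All intervals are 0-based half-open `[start, end)` on named chromosomes
(BED convention); SAM input is converted at the boundary and positions
round-trip exactly. Strand `"."` marks strand-agnostic features (windows,
segments). Containers are plain data frames; IRanges does the interval
arithmetic and Biostrings the FASTA handling behind the reader/writer
surface.

Methylation calls are kept **per cytosine and per strand**: the plus-strand
C and the minus-strand C of one CpG are separate records (a plus-strand
read reports C/T at the C; a minus-strand read reports G/A at the G). This
preserves single-cytosine granularity for display and filtering;
`collapse_strands()` pools the pair when coverage matters more than
strandedness. Whether region averages should be coverage-weighted or
per-cytosine means is genuinely ambiguous in this kind of analysis; the
coverage-weighted mean (pooled counts) is the default and the unweighted
mean is an option on `window_methylation()` and `paired_table()`.

## Key procedures and their parameters

### Weighted IP quantification

Multi-mapping reads are retained up to their reported placements and each
alignment is weighted by the inverse of the number of hits, so every read
contributes exactly one unit of mass (`shift_and_weight()` asserts this
invariant in tests). Alignments are collapsed to a single tag at the
5' position shifted by **60 bp** — half of the **120 bp** fragment length —
so tags approximate fragment midpoints. The shift is a parameter; fragment
length estimation is out of scope.

### Differential hMeDIP windows

The genome is tiled into **1 kb** windows overlapping by **500 bp**,
starting at 0 on each chromosome. Each window is scored

\[
\log_2 FC = \log_2\frac{n_{NP}/N_{NP}\cdot m + p}{n_{ES}/N_{ES}\cdot m + p},
\qquad m = \min(N_{ES}, N_{NP}),\; p = 8,
\]

with `n` the summed weights of overlapping alignments and `N` the library
sizes. The pseudocount `p` keeps low-count windows from being dominated by
sampling noise; the formula is antisymmetric under condition swap and
shrinks to 0 as `p` grows (both are tested properties). Windows with
`log2FC > 3` (or `< -3`) in **both** biological replicates — strict
inequalities, so a window at exactly 3.0 is unflagged — are merged into
gain (loss) regions; overlapping or book-ended windows merge, which with
the default 500 bp step is the same thing.

Two details are not fixed by the procedure's usual description and are
explicit choices here, both config-exposed:

- **Tiling phase and trailing windows.** Windows start at 0; full windows
  are emitted while they fit, and one trailing partial window is kept only
  if it is at least `step` long *and* extends coverage beyond the last full
  window (a 2,500 bp chromosome yields starts 0, 500, 1000, 1500 and
  nothing more).
- **Replicate handling.** Windows are flagged on the per-replicate rule and
  the flagged windows merged; pooled-count region boundaries would be a
  different (also defensible) convention.

### Segment enrichment

For each region class (gain/loss) and segment type (FMR/UMR/LMR crossed
with cell-type specificity), enrichment is observed overlapping bases
divided by expected bases, where expected = (segment fraction of the
genome) × (total region bases). Each segment type is normalized
independently, the literal reading of that definition. Genome size is the
full toy-assembly length (no gap masking; `effective_genome_size` would be
the knob on real data). Types with zero bases give `NA`, never infinity.

### ChIP-BisSeq vs WG-BisSeq pairing

Paired units are 200 bp windows centered at motif centers (center
convention: `start + floor(width/2)`). A window enters the comparison only
if **all** considered cytosines — every CpG cytosine observed in either
sample within the window — reach **10×** coverage in **both** samples. The
order of pooling and filtering matters in principle; replicate pooling, if
any, happens before the coverage filter here. The per-cytosine variant
pairs individual positions under the same joint rule and measures distance
to the nearest bound motif center (ties broken to the leftmost center, for
determinism).

### Motif scanning

Log2-odds scores against a background distribution, both strands, with a
0.01 pseudocount on PWM rows so only `N` bases score `-Inf`. Gapped motifs
allow an unscored variable linker (default range 0–11 nt) after a fixed
position (9 for the REST-like example); the score at a start is the maximum
over linker lengths and equals brute-force enumeration (tested), with ties
going to the smallest linker. Overlapping same-strand hits are resolved
greedily by descending score — the resolution method is a choice, and can
be disabled. The shipped matrices (`example_pwm()`,
`inst/extdata/*_synthetic.pwm`) are synthetic illustrations constructed for
this package; real scans should load the user's matrices via `read_pwm()`,
and the score threshold is always explicit.

### Enrichment classification

Site-level ChIP enrichment uses the same min-library-scaled, pseudocounted
log-ratio as the differential windows; this normalization is a
reconstruction (the upstream ChIP pipeline it imitates is not restated in
the sources this design follows) and is exposed entirely through
parameters. Sites are partitioned by two ordered thresholds, default
**(1, 3)** log2 units, into unbound / weakly bound / strongly bound. The
running mean that summarizes methylation along the enrichment axis uses a
centered window of **k = 101 points** (shrunk with a warning on small
inputs; k = 1 returns the raw points) — k is a smoothing choice, not a
derived quantity.

## What the generator emulates — and what it does not

`make_genome()` draws i.i.d. bases at a given GC content (default 0.42,
mammalian-like), giving a realistic CpG density for CpG-poor regions;
optional islands can be enriched. `plant_motifs()` writes consensus or
PWM-sampled instances (with random linkers for gapped motifs) and records
the ground truth. `simulate_molecules()` draws per-molecule binding and
methylation state; methylation is molecule-level (all CpGs of a molecule
share a state) and symmetric across strands, which is the cleanest
embodiment of the static/unlinked dichotomy. `simulate_bisulfite_reads()`
converts unmethylated cytosines with the configured rate (default 0.99;
both 5mC and 5hmC resist conversion, as in the real assay) and emits
pre-aligned reads; `simulate_ip_reads()` samples fragment centers from a
piecewise-constant signal-plus-background track and fabricates
multi-mapping structure by decoy placements sharing a read id.

Defaults that define the simulated study conditions:

- ChIP-BisSeq non-specific pulldown: **2%** of the library (a clean ChIP);
  hMeDIP non-specific background: **10%**.
- Per-site occupancy (static) and demethylation (unlinked) probabilities:
  Uniform(0.5, 0.9) draws, giving ~30% marginal methylation with
  between-site variation, as across real LMRs.
- Gradient IP amplitude: site signal weight `24 × occupancy` over a uniform
  background of 1, placing occupancy tiers 0 / 0.3 / 0.9 well inside the
  unbound / weak / strong bands of the (1, 3) thresholds.
- Turnover study: two 2.5 Mb chromosomes; 20 NP-specific and 20
  ES-specific 5 kb LMRs (2% of the genome each), 40 constitutive 2 kb
  LMRs, 20 UMRs, FMR elsewhere; 5hmC signal 40× background at the
  state-specific LMRs and 20× at constitutive ones; 100k reads per hMeDIP
  library, two replicates per state; reciprocal methylation turnover
  (60% ↔ 20%) at the state-specific LMRs. A signal-to-background ratio
  meaningfully above 8 is a *requirement*, not a tuning: with pseudocount
  `p` the scaled ratio `(8x + p)/(x + p)` is below 8 for every positive
  `x`, so a planted ratio of exactly 8 can never clear the |log2FC| > 3
  rule; 40× reflects the strong overrepresentation regime the analysis is
  designed to detect.

Not modeled: sequencing errors, PCR duplicates, fragment-length
distributions, CpG-density heterogeneity beyond islands, hemimethylation,
partial molecule-level methylation mosaicism, and real alignment (reads
are emitted pre-aligned; multi-mapping is simulated, not discovered).
Passing tests therefore demonstrate that the *analysis logic* recovers
planted truth under faithful assay arithmetic — not that the pipeline is
robust to every artifact of real libraries.

## Numerical and degenerate-input conventions

- Zero-coverage windows return an `NA` sentinel and are excluded
  downstream, with counts logged; correlation summaries return `NA` under
  zero variance rather than erroring.
- Tags shifted off a chromosome end are clamped and counted; anchors whose
  profile flank leaves the chromosome are dropped and counted.
- `scan_pwm()` warns and returns an empty frame when the threshold exceeds
  the attainable score; `filter_coverage()` keeps `n_total >= min_cov`
  (10× means 10 is kept, 9 is not).
- Unsorted bedGraph input is an error, never silently reordered.
- All generators restore the caller's RNG state and are byte-deterministic
  under a fixed seed; derived seeds stay below 2^31.

## Problem sizes

The test suite and the acceptance script run the scenario comparison at 40
sites with 50× coverage, the gradient at 300 sites with 200k-read IP
libraries, and the turnover study on the 5 Mb genome described above —
sizes chosen so each planted effect is recovered with a comfortable
statistical margin while a full run stays in the minutes range on one CPU.
The same machinery scales to larger designs by raising the size parameters.

## Known limitations

Genome-scale numbers from real datasets (correlations across millions of
CpGs, fractions of predicted sites with motif CpGs, and the like) depend on
real genome structure and cannot be reproduced from synthetic uniform
genomes; the package's validation is therefore property-based: planted
scenarios must be discriminated, planted regions recovered, and exact
formulas reproduced. The enrichment normalization for single-site
classification is a parameterized reconstruction, and the bound/unbound
thresholds have no canonical values — both should be treated as analysis
settings, reported alongside results.
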