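Package: methturnover
Title: Transcription Factor Occupancy and DNA Methylation Turnover at
    Low-Methylated Regions
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools to relate transcription-factor occupancy to DNA
    methylation heterogeneity and 5-hydroxymethylcytosine (5hmC) turnover
    at low-methylated regions (LMRs). Implements per-cytosine methylation
    calling from bisulfite alignments, ChIP-BisSeq versus whole-genome
    BisSeq comparison with joint coverage filtering, position-weight-matrix
    motif scanning with an optional variable-length linker,
    inverse-hit-weighted quantification of immunoprecipitation libraries,
    sliding-window differential hMeDIP analysis with a pseudocount
    fold-change rule and dual-replicate thresholding, observed/expected
    base-overlap enrichment of region classes in methylome segments, and a
    synthetic-data generator that plants known occupancy, methylation and
    hydroxymethylation ground truth for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Biostrings,
    IRanges,
    S4Vectors,
    jsonlite,
    stats,
    tools,
    utils,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
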