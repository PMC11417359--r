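Package: velotrend
Title: Transcription Kinetics, Trend-Anomaly Classification and Promoter
    Target Mapping for Two-Sample Single-Cell RNA Velocity Studies
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Tools to study stalled differentiation from spliced/unspliced
    single-cell counts. Simulates two-sample (wild-type and knockout-like)
    data under a two-state transcription-kinetics model with induction,
    repression and steady gene classes; fits per-gene kinetics by an
    alternating least-squares scheme to recover rates, latent cell time and
    a fit likelihood that defines trajectory driver genes; builds a
    velocity-derived cell-cell transition Markov chain with terminal-state
    scores and a cluster-graph abstraction; classifies per-gene trend
    anomalies between samples with a Mann-Kendall / slope-ratio rule; and
    intersects anomalous drivers with promoter-bound targets defined by
    peak-to-gene annotation and a degenerate GAA-motif / heat-shock-element
    grammar. Includes cell QC, log-normalization, highly-variable-gene
    selection, pseudobulk cluster correlation and a rank-test differential
    expression screen.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Matrix,
    Biostrings,
    GenomicRanges,
    IRanges,
    S4Vectors,
    jsonlite,
    yaml,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    deSolve
Config/testthat/edition: 3
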