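Package: memorychrom
Title: Sequence-Directed Chromatin Analysis of Transcriptional Memory at
    General Regulatory Factor Targets
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Analysis toolkit for distinguishing "memory effect" from
    transcriptionally responsive targets of an essential yeast general
    regulatory factor (Abf1). Implements ChIP-seq tag extension, per-base
    coverage and genome-wide Z-score normalization, motif- and TSS-centered
    meta-profiles, a poly(dA:dT) 7-mer nucleosome-disfavoring sequence
    statistic with windowed profiles, A-tract/T-tract decomposition and
    cross-species application, position weight matrix log-odds scoring with a
    two-standard-deviation site-conservation criterion, fold-change-based
    target classification, and bootstrap comparison of per-gene metrics such
    as expression noise and mRNA half-life. A synthetic-data generator
    reproduces the statistical structure the analysis assumes so the whole
    pipeline is testable without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Biostrings,
    GenomicRanges,
    IRanges,
    methods,
    S4Vectors,
    stats,
    tools,
    utils,
    yaml
Suggests:
    jsonlite,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
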