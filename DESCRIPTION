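Package: crmbench
Title: Evaluation and Robust High-Density Prediction of Cis-Regulatory Modules
Version: 0.1.0
Authors@R: person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: A pipeline for benchmarking enhancer / cis-regulatory module (CRM)
    prediction methods against a database of experimentally validated CRMs
    (REDfly-style), and for producing predictions that are robust to the
    placement of the first scoring window. Provides interval-overlap
    performance measures with permutation-based random expectation, a
    supervised fixed-order Markov window scorer with per-instance offsets, a
    high-density protocol that pools 25 offset instances into 10-bp summed
    score bins with peak calling and a two-stage elbow cutoff, a genome
    fragmentation simulator for assessing robustness to assembly quality, and
    a seeded synthetic-fixture generator with planted, class-labelled CRMs.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    methods,
    stats,
    utils,
    tools,
    Rcpp,
    GenomicRanges,
    IRanges,
    S4Vectors,
    GenomeInfoDb,
    Biostrings,
    rtracklayer,
    yaml
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    optparse,
    jsonlite,
    withr
Config/testthat/edition: 3
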