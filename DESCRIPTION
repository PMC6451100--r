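Package: hissa
Title: Sequence Specificity Analysis of Single-Stranded RNA Loading from
    Randomized-Oligo IP/Input Sequencing
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Quantifies sequence preferences in single-stranded RNA loading
    onto Argonaute proteins from high-throughput sequencing of partially
    randomized oligo libraries (HISSA: HIgh-throughput Sequencing mediated
    Specificity Analysis). Provides structural read parsing against a
    declared oligo architecture, UMI-based deduplication with iterative
    Hamming-distance error elimination, per-sequence and per-position
    enrichment statistics, k-mer motif enrichment, pairwise positional
    interaction regression with stepwise selection, an annotation-based
    filter cascade for endogenous mRNA-fragment reads with exact-test motif
    enrichment, and a synthetic-experiment simulator with recorded ground
    truth for calibration and parameter-recovery testing.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    methods,
    stats,
    utils,
    Biostrings,
    IRanges,
    GenomicRanges,
    S4Vectors,
    rtracklayer
Suggests:
    testthat (>= 3.0.0),
    optparse,
    jsonlite
Config/testthat/edition: 3
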