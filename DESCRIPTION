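Package: covmine
Title: Targeted Coverage Mining for Low-Abundance Transcript Detection
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Toolkit for mining targeted genomic windows across many
    independent RNA-seq datasets to detect weakly expressed, non-polyadenylated
    transcripts that single datasets cannot resolve. Reads SAM alignments,
    applies quality and region read-pair filters, computes CIGAR-aware per-base
    depth of coverage, collapses coverage across datasets into a composite
    signal, calls expressed segments and splice junctions, scores sliding-window
    percent-identity conservation on gapped alignments, scans IUPAC transcription
    factor binding motifs, and quantifies expression from qPCR Ct tables by the
    comparative delta-Ct method. A seeded read simulator reproduces the
    weak-transcript regime so every stage is testable end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    BiocGenerics,
    Biostrings,
    dplyr,
    generics,
    ggplot2,
    purrr,
    readr,
    rlang,
    stats,
    stringr,
    tibble,
    tidyr,
    utils
Suggests:
    jsonlite,
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
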