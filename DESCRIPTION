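Package: vipseq
Title: Detection and Absolute Quantification of Spontaneously Induced
    Prophages from Virion Sequencing
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for virion induction profiling from sequencing of
    encapsidated phage DNA. Detects active prophages in a lysogen genome
    from virion-read coverage islands, refines exact attL/attR boundaries
    from discordant and split junction-spanning read pairs, converts eluted
    DNA mass and per-prophage read fractions into absolute virion titres,
    computes assay detection limits and induction rates, benchmarks in
    silico prophage predictions against experimentally active prophages,
    clusters prophages by intergenomic similarity into strain phagotypes
    and scores within-phagotype protection, and simulates virion read
    pools with junction-spanning pairs and lateral-transduction coverage
    gradients for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    Biostrings,
    GenomicAlignments,
    IRanges,
    Rsamtools,
    S4Vectors,
    dplyr,
    generics,
    ggplot2,
    igraph,
    purrr,
    readr,
    rlang,
    stats,
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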