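Package: repscout
Title: Discovery, Characterization and Dating of Genome-Specific Composite Repeats
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for discovering composite repetitive elements that are
    specific to one genome of a related pair, such as the tandem-repeat plus
    conserved-sequence motifs harboured in degraded LTR retrotransposons of
    the Gossypium D genome. Provides bespoke seed-and-extend local alignment
    with 80-80-rule presence/absence screening, tandem-repeat array detection
    with unit-consensus training, constituent pairing into composite motifs,
    consensus-accumulation profiling, paired-LTR detection with Kimura
    two-parameter dating (T = d/2r), chromosomal-distribution chi-square
    statistics, synteny-block chaining, and a fully ground-truthed synthetic
    genome-pair simulator for end-to-end validation without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    Biostrings,
    IRanges,
    GenomicRanges,
    S4Vectors,
    rtracklayer,
    dplyr,
    tidyr,
    purrr,
    tibble,
    readr,
    ggplot2,
    generics,
    jsonlite,
    rlang,
    stats,
    utils,
    tools
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
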