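Package: gofscreen
Title: Gain-of-Function Transposon Screen Hit Calling and Transcriptional
    Rescue Analysis
Version: 0.1.0
Authors@R: person("Package", "Maintainer", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Analysis toolkit for piggyBac gain-of-function suppressor
    screens and the companion transcriptomics. Collapses splinkerette-seq
    integration records into unique TTAA sites, assigns sites to genes
    within a configurable window, and calls candidate suppressor genes
    against a TTAA-density binomial null with Benjamini-Hochberg control.
    Implements gene filtering, median-of-ratios normalisation and per-gene
    negative-binomial Wald differential expression; classifies
    disease-signature genes as transcriptionally rescued by a suppressor;
    provides exact overlap (binomial), over-representation
    (hypergeometric) and promoter motif (Fisher) enrichment tests with a
    JASPAR PFM scanner. Ships a synthetic-data module (toy genomes with
    planted integrations, negative-binomial count matrices with planted
    effects, promoters with planted motifs) so every stage is testable
    offline against ground truth, plus a command-line pipeline driver.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    Biostrings,
    GenomicRanges,
    IRanges,
    S4Vectors,
    rtracklayer,
    jsonlite,
    methods,
    stats,
    tools,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
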