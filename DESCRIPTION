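Package: dieldhs
Title: Diel DNase-Seq Chromatin Accessibility Analysis with Planted-Truth Simulation
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: An end-to-end pipeline for diel (day/night) DNase-seq regulatory
    analysis of plant leaf tissues: fragment-size filtering, Poisson
    local-background peak calling of DNase I hypersensitive sites (DHSs) with
    q-value control, irreproducible discovery rate (IDR) reconciliation of
    replicates, strand-aware genomic annotation of peaks relative to genes,
    negative-binomial differential accessibility and expression testing,
    identification of coordinately changed genes (CCGs), position weight matrix
    scanning with exact discretized-score p-values, and construction of
    TF-to-target regulatory networks from motif occurrences in open chromatin.
    Ships a synthetic-data generator that plants DHSs, condition-specific
    accessibility, coordinated expression and motif instances into a miniature
    genome, so every stage is testable against known ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.2)
Imports:
    methods,
    stats,
    utils,
    tools,
    S4Vectors,
    IRanges,
    GenomicRanges,
    Biostrings,
    rtracklayer
Suggests:
    testthat (>= 3.0.0),
    jsonlite
Config/testthat/edition: 3
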