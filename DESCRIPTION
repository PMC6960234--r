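Package: barcodekit
Title: Multi-Locus DNA Barcoding Analysis: Quality Screening, Barcode-Gap
    OTU Delimitation and Pseudogene Screening
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: An end-to-end toolkit for two-marker (COI + 16S) DNA-barcoding
    surveys: Phred/length quality screening of sequence sets, pairwise
    distances under the p, Jukes-Cantor (JC69) and Kimura two-parameter
    (K2P) models with pairwise deletion, BIONJ neighbour-joining trees with
    nonparametric bootstrap support, Automatic Barcode Gap Discovery (ABGD)
    OTU delimitation over a geometric prior series with recursive
    partitioning, cross-marker OTU reconciliation with a divergence-based
    conflict rule, novelty and contamination classification against a local
    reference library, mitochondrial pseudogene (NUMT) screening
    (reading-frame stops, frameshifts, GC-content outliers, cross-marker GC
    correlation), and OTU/morphospecies concordance reporting.  A synthetic
    two-marker data generator with known species truth supports testing of
    every stage.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    ape,
    Biostrings,
    jsonlite,
    methods,
    stats,
    utils
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
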