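Package: apeg
Title: Epigenome-Sensitive Thermodynamic Modeling of Transcription Factor
    Binding
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Predicts transcription factor (TF) occupancy of cis-regulatory
    sequences with a statistical-thermodynamic model in which the affinity of
    each PSWM-scanned binding site is modulated by the local intensities of
    epigenomic marks (histone modifications, DNA methylation). Provides exact
    partition-function computation over binding-site configurations by dynamic
    programming with a brute-force enumeration oracle, correlation-maximizing
    estimation of mark influence parameters ("epigenomic motifs") and binding
    cooperativity from genome-wide binding data, permutation tests against
    intensity-shuffled tracks, constraint-based simulations of transcriptional
    noise and of the epigenomic boost of weak-site cooperativity, strong/weak
    binding-site analyses, and inter-individual binding-variation statistics.
    Includes a seeded synthetic-data generator and a command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    Rcpp,
    stats,
    utils,
    tools,
    jsonlite,
    yaml,
    optparse,
    Biostrings,
    GenomicRanges,
    IRanges,
    rtracklayer
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr,
    knitr,
    rmarkdown
VignetteBuilder: knitr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
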