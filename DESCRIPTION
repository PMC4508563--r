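Package: parcupan
Title: Comparative Pan-Genome Analysis for Reduced Bacterial Genome Bins
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Comparative-genomics toolkit for sets of reconstructed (metagenome-
    or single-cell-derived) bacterial genome bins, built around the highly
    reduced Parcubacteria (OD1) genomes. Provides exact Smith-Waterman
    all-vs-all protein alignment, bidirectional-best-hit orthology with an
    AAI-adaptive identity filter and Markov clustering, core/flexible
    partitioning, median-normalized pan-genome accumulation curves with
    power-law fits, conserved single-copy-gene completeness and contamination
    scoring, windowed GC/tetranucleotide composition signatures, tRNA
    anticodon-loop nucleotide-usage profiling, and a synthetic genome-set
    generator with planted ground truth for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Biostrings,
    Matrix,
    igraph,
    jsonlite,
    Rcpp,
    methods,
    stats,
    utils,
    tools
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    mclust,
    withr
Config/testthat/edition: 3
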