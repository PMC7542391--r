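Package: ltrclock
Title: Molecular-Clock Dating of LTR Retrotransposon Insertions and
    Repeat-Landscape Analysis of Fungal Genomes
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Tools for quantifying how long-terminal-repeat (LTR)
    retrotransposon activity shaped a genome. Estimates per-element
    insertion ages from the divergence of an element's twin terminal
    repeats under a molecular clock (T = K/2r, with Jukes-Cantor or
    Kimura two-parameter correction), builds superfamily-stacked
    insertion landscapes, scans genomes for repeat-induced point
    mutation (RIP) with the TpA/ApT product and (CpA+TpG)/(ApC+GpT)
    substrate dinucleotide indices, tests gene-family enrichment in
    LTR-flanking regions with exact and chi-square machinery, and
    computes assembly and composition statistics (N50, GC, repeat and
    coding fractions). A seeded synthetic-genome generator plants genes
    and LTR elements of known insertion age, with optional RIP-like
    hypermutation, so every stage can be validated against ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Biostrings,
    GenomicRanges,
    GenomeInfoDb,
    IRanges,
    S4Vectors,
    rtracklayer,
    Rcpp,
    jsonlite,
    yaml,
    methods,
    stats,
    tools,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
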