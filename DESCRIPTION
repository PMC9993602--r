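Package: plastomeKit
Title: Comparative Structural Analysis of Plastid Genomes
Version: 0.99.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for comparative structural analysis of circular plastid
    genomes (plastomes): detection of the inverted-repeat pair and the
    quadripartite LSC/IRb/SSC/IRa partition with junction gene contexts and
    boundary-shift comparison; cataloguing of nonredundant non-tandem
    repeats (direct and inverted, >= 30 bp) with gene-context hotspot
    summaries; homology-based gene and pseudogene calling via a seeded
    affine-gap local aligner with BLASTn-style scoring; IR-reduced synteny
    block construction, signed-permutation rearrangement typing and
    breakpoint distances; and detection of repeat-mediated isomeric
    plastome configurations from long reads, including junction-window
    spanning-read counting and isomer frequency estimation. A deterministic
    synthetic-plastome and long-read generator provides fully specified
    fixtures for every analysis stage.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    Rcpp,
    Biostrings,
    IRanges,
    GenomicRanges,
    S4Vectors,
    rtracklayer,
    jsonlite
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
biocViews: Genetics, SequenceMatching, Alignment, ComparativeGenomics
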