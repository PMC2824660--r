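Package: plastex
Title: Tandem Repeats, Profile Search, and Exon Reconstruction for
    Alternatively Spliced Regions
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Toolkit for comparative analysis of rapidly evolving,
    alternatively spliced gene regions built around a tandem-repeat exon,
    as in the C-terminal region of vertebrate periostin. Provides tandem
    repeat period estimation, unit segmentation and consensus calling with
    sequence-logo information content, windowed dot-matrix similarity with
    forward and reverse-complement diagonal detection, position-specific
    scoring matrix construction and calibrated database scanning with
    iterative refinement, homology-guided exon reconstruction with
    canonical GT-AG splice-site validation, region-wise neighbor-joining
    phylogenies with bootstrap support, and a synthetic-locus generator
    for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Biostrings,
    rtracklayer,
    BiocGenerics,
    S4Vectors,
    GenomeInfoDb,
    ape,
    phangorn,
    Rcpp,
    yaml,
    stats,
    utils,
    grDevices,
    graphics,
    methods
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
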