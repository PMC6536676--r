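Package: viromeKit
Title: Prophage Mining, Attachment-Site Discovery and Phage Similarity Networks
Version: 0.99.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A toolkit for characterising the temperate-phage content of
    bacterial genomes. Provides completeness screening of candidate prophage
    regions from module-labelled annotations, GC-contrast boundary
    refinement, discovery of attL/attR direct repeats with tRNA 3'-end
    reconstitution checks and attB/attP derivation, an exact Smith-Waterman
    local-alignment engine with Karlin-Altschul E-values, reciprocal
    protein-similarity (gene-sharing) networks, all-vs-all nucleotide ribbon
    comparison of phage genomes, and census statistics over a packaged
    virome catalog of the genus Paracoccus. A synthetic-data generator
    plants prophages, attachment-site duplications, GC contrast and protein
    homolog clusters with machine-readable truth so that every stage is
    testable without external downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3.0)
Imports:
    methods,
    stats,
    utils,
    tools,
    Rcpp,
    Biostrings,
    IRanges,
    S4Vectors,
    GenomicRanges,
    rtracklayer,
    igraph,
    xml2,
    withr
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    optparse
biocViews: Genetics, SequenceMatching, Alignment, Network, Microbiome
Config/testthat/edition: 3
RoxygenNote: 7.3.3
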