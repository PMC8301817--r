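Package: lhrfam
Title: Phylogenomic Classification of Lhr-Type SF2 Helicases
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: A desk-scale phylogenomic pipeline for classifying Lhr-type
    superfamily-2 helicases into families: profile-hit candidate filtering,
    all-against-all local alignment with Karlin-Altschul E-values,
    best-bidirectional-hit similarity graphs, Markov Clustering with an
    inflation-stability scan, identity-pruned medoid dereplication,
    Pfam-style domain-architecture family assignment, helicase-core
    extraction, alignment trimming and concatenation, gene-neighborhood
    microsynteny profiling, and tree/cluster concordance checks. Includes a
    synthetic-data generator that plants family structure, domain
    architectures and genomic contexts with known ground truth, so every
    stage is testable without genome downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    Biostrings,
    igraph,
    Matrix,
    ape,
    phytools,
    mclust,
    rtracklayer,
    withr,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    jsonlite
Config/testthat/edition: 3
RoxygenNote: 7.3.3
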