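Package: syntnet
Title: Phylogenomic Synteny-Network Analysis of Focal Gene Families
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Builds and analyses weighted synteny networks for a focal gene
    family (such as the plant type III polyketide synthases) across multiple
    genomes. Detects collinear blocks between chromosome gene orders by
    anchor chaining under detector profiles emulating MCScanX and i-ADHoRe
    (native outputs of either tool can be imported instead), clusters
    homology graphs with Markov clustering, collapses tandem arrays into
    regions, combines the evidence of two detectors crossed with two family
    clusterings into a weighted network, derives robust syntenic clusters by
    consensus of four community-detection algorithms consolidated with
    affinity propagation, and tests clusters and syntenic regions for
    reaction-type and GO-term enrichment (one-sided Fisher tests with
    Benjamini-Hochberg correction and enrichment-map style term similarity).
    A built-in genome-evolution simulator (speciation along a tree,
    whole-genome/segmental/tandem duplication, loss, inversion,
    translocation) provides fully labelled synthetic datasets so every stage
    is testable without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    igraph,
    Matrix,
    ape,
    jsonlite,
    yaml,
    stats,
    utils,
    Rcpp
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
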