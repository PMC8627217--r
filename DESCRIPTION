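Package: mobelem
Title: Delineation and Comparative Analysis of Integrative and Conjugative
    Elements in Rhizobial Genomes
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Detects conjugation and mobilization machinery in annotated
    bacterial genomes, delineates integrative and conjugative elements (ICEs,
    including tripartite ICEs) and integrative mobilizable elements (IMEs)
    through integrase-associated att-site direct repeats, classifies elements
    (ICE, IME, conjugative or mobilizable plasmid), partitions element gene
    content into backbone and accessory clusters, quantifies the mobilome
    share of the pangenome, and detects inter-element recombination with an
    alignment-free longest-match statistic. Ships a synthetic-genome simulator
    that plants elements with full ground truth so every stage is testable.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.2)
Imports:
    Biostrings,
    IRanges,
    GenomicRanges,
    S4Vectors,
    rtracklayer,
    ape,
    igraph,
    jsonlite,
    Rcpp,
    stats,
    tools,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    optparse,
    phangorn,
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
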