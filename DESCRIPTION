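Package: panphylo
Title: Pan-Genome, Supertree and Gene Gain/Loss Analysis of Bacterial
    Genome Families
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Comparative genomics toolkit for families of bacterial genomes,
    built around the analysis of the Bifidobacteriaceae: all-vs-all exact
    protein alignment and Markov clustering into clusters of orthologous
    groups, pan/core-genome partitioning with open/closed pan-genome
    assessment, truly-unique-gene extraction, a neighbor-joining core-genome
    supertree with bootstrap support, fragment-based average nucleotide
    identity for species delineation, glycosyl-hydrolase repertoire
    statistics, and Dollo-parsimony reconstruction of gene gain and loss
    along the tree. Includes a genome-family simulator with full ground
    truth (known tree, gene-family histories, controlled sequence
    divergence) for validating every stage.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    methods,
    stats,
    utils,
    Biostrings,
    IRanges,
    ape,
    phangorn,
    jsonlite,
    withr
Suggests:
    testthat (>= 3.0.0),
    mclust
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
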