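Package: structcore
Title: Structural Core-Gene Identification and Phylogenomics from 3Di Proteomes
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Identifies single-copy structural core genes from paired
    amino-acid/3Di proteomes by quasilinear greedy clustering on combined
    structural and sequence similarity, builds progressive multiple structural
    alignments in 3Di space, projects them back to amino acids, concatenates
    them into a partitioned supermatrix, and infers and evaluates species
    phylogenies (neighbor joining with bootstrap, minimum-ancestor-deviation
    rooting, quartet similarity, ultrametricity). Includes a synthetic proteome
    generator with a known species tree and planted gene families for
    end-to-end validation, including the twilight-zone regime where amino-acid
    identity decays below 30% while structural strings stay conserved.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    ape,
    Biostrings,
    tibble,
    dplyr,
    purrr,
    rlang,
    generics,
    ggplot2,
    jsonlite,
    mclust,
    yaml,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
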