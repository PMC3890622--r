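Package: famsyn
Title: Protein Family Delineation and Gene Lineage Inference from
    Similarity Networks and Synteny
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Delineates protein families by breadth-first traversal of an
    all-vs-all pairwise similarity network constrained at E-value
    thresholds, and reconstructs gene lineages across genomes from
    conserved gene neighbourhoods (shared homologous neighbour pairs).
    Includes exact affine-gap local and global alignment with
    Karlin-Altschul E-value statistics, a hydropathy-based transmembrane
    segment filter for full-size transporter screening, per-cluster
    identity/similarity summaries, distance-based neighbor-joining trees,
    and a genome-evolution simulator (duplication, loss, whole-genome
    duplication, horizontal transfer, rearrangement) that provides ground
    truth for validating the whole pipeline.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    Rcpp,
    Biostrings,
    ape,
    igraph,
    dplyr,
    tidyr,
    purrr,
    tibble,
    readr,
    stringr,
    rlang,
    ggplot2,
    generics,
    yaml,
    stats,
    tools,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    phangorn,
    mclust,
    jsonlite,
    optparse,
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
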