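Package: magderep
Title: Dereplication of Metagenome-Assembled Genomes by MinHash
    Pre-Clustering and Fragment-Based ANI
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools to remove redundant metagenome-assembled genomes (MAGs)
    from genome sets assembled independently across samples. Genomes are
    first grouped with MinHash (Mash-style) sketch distances and
    hierarchical clustering, then compared within groups by fragment-based
    average nucleotide identity (ANI) with per-genome alignment coverage;
    pairs exceeding ANI and coverage thresholds in both directions are
    collapsed to the representative with the best completeness and
    contamination estimates. Includes evaluation procedures for the effect
    of genome completeness and coverage thresholds on dereplication, for
    pangenome gene-cluster retention, and for read-coverage dilution caused
    by database redundancy, together with a synthetic conspecific-MAG
    generator with known ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Biostrings,
    dplyr,
    generics,
    ggplot2,
    igraph,
    jsonlite,
    purrr,
    Rcpp,
    readr,
    rlang,
    stats,
    stringr,
    tibble,
    tidyr,
    utils,
    withr
LinkingTo: Rcpp
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
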