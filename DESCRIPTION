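Package: convloss
Title: Forward-Genomics Screening for Convergent Gene Loss
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: A phylogeny-aware screen for protein-coding genes convergently
    lost in lineages sharing a derived phenotype. Detects gene-inactivating
    mutations (frameshifts, premature stop codons, splice-site mutations,
    exon and gene deletions) in codon alignments, summarizes them as the
    maximum percent of the reading frame left intact, associates per-gene
    intactness with a binary or continuous phenotype by phylogenetic
    generalized least squares under a Brownian-motion covariance with
    Benjamini-Hochberg false-discovery-rate control and a convergence filter,
    maps loss events onto the species tree by Dollo parsimony, and tests
    candidate sets for gene-set over-representation. Includes a synthetic
    phylogenomic data generator with implanted mutation histories so every
    stage is testable end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    ape,
    stats,
    graphics,
    utils
Suggests:
    testthat (>= 3.0.0),
    nlme,
    jsonlite,
    yaml,
    optparse,
    withr
Config/testthat/edition: 3
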