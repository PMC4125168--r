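Package: genedecay
Title: Gene Loss, Pseudogene Annotation, and Branch-Model Tests of Relaxed Selection
Version: 0.1.0
Authors@R: person("Package", "Maintainer", email = "maintainer@example.org", role = c("aut", "cre"))
Description: A pipeline for studying loss and decay of a protein-coding gene
    across species: reconstruction of exon sets and virtual cDNAs from genomic
    sequence against a reference gene model, cataloguing of open-reading-frame
    disrupting mutations (frameshifts, premature stops, start-codon loss,
    splice-site mutations, exon and whole-gene deletions), placement of shared
    mutations on a species tree by Dollo-style parsimony, gene presence/absence
    calling from whole-genome shotgun reads, and maximum-likelihood fitting of
    Goldman-Yang codon substitution models with branch-specific dN/dS classes,
    including likelihood-ratio tests of relaxed selection. A synthetic-data
    module generates multi-exon loci with planted mutations, read sets, and
    codon alignments evolved under known branch-specific dN/dS so every stage
    is testable with known ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    ape,
    Biostrings,
    BiocGenerics,
    jsonlite,
    methods,
    Rcpp,
    stats,
    utils
LinkingTo: Rcpp, RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    Matrix,
    withr,
    optparse
Config/testthat/edition: 3
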