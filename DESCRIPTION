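Package: attCfold
Title: Folding Thermodynamics and Replication-Strand Analysis of Integron attC Sites
Version: 0.99.0
Authors@R: person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Tools to study the determinants of gene-cassette excision in
    bacterial integrons. Models attC recombination sites (R''/L''/VTS/L'/R'
    box architecture), computes minimum-free-energy structures and ensemble
    free energies of their single strands under a nearest-neighbor stacking
    model with hard recombinogenic constraints, and derives the pfold
    statistic (Boltzmann probability of the recombinogenic fold). Includes
    replichore geometry (GC-disparity profiles, leading/lagging-strand-template
    classification of cassette arrays), cassette and CDS length metrics,
    SCI/MI classification, nucleotide skews, pairwise identity and direct
    repeats, rank-sum tests and regressions, a synthetic-data generator with
    planted ground truth, and an optional RNAfold (ViennaRNA) DNA-parameter
    backend.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    tools,
    Rcpp,
    S4Vectors,
    IRanges,
    GenomicRanges,
    Biostrings,
    rtracklayer,
    jsonlite
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
biocViews: Genetics, SequenceMatching, SecondaryStructure, Annotation
Collate: 
    'attCfold-package.R'
    'AllGenerics.R'
    'AttCSite-class.R'
    'RcppExports.R'
    'constraints.R'
    'boxes.R'
    'energy-model.R'
    'fold.R'
    'replichore.R'
    'synthetic.R'
    'io.R'
    'stats.R'
    'vienna.R'
    'pipeline.R'
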