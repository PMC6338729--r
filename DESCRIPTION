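Package: spatprot
Title: Subcellular Spatial Proteomics from Organelle Fraction Profiles
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Downstream analysis of correlation-profiling spatial proteomics
    experiments (LOPIT-style TMT fraction profiles). Provides a
    SummarizedExperiment-based container for protein fraction profiles,
    sum-normalisation and protein-group aggregation, marker management,
    principal component projection, marker-trained support vector machine
    classification of protein subcellular localisation with score-ordered
    false discovery rate thresholding, the QSep cluster-resolution statistic,
    theta-weighted k-nearest-neighbour transfer learning for integrating a
    primary and an auxiliary map, selection-bias-corrected category
    over-representation analysis of the unclassified proteome, and a
    synthetic-data generator with known ground truth for end-to-end testing.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3), methods, SummarizedExperiment
Imports: stats, utils, tools, S4Vectors, Rcpp, jsonlite, yaml
LinkingTo: Rcpp
Suggests: testthat (>= 3.0.0), quadprog
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Collate:
    'AllGenerics.R'
    'AllClasses.R'
    'core.R'
    'synthetic.R'
    'svm.R'
    'transfer.R'
    'qsep.R'
    'enrichment.R'
    'pipeline.R'
    'plots.R'
    'RcppExports.R'
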