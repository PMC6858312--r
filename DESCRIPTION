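Package: OncoVote
Title: Cancer-Type Classification from Somatic Alterations with a
    Soft-Voting Ensemble
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Builds a five-group somatic-alteration feature matrix
    (gene-level mutation profiles, mutation rates, the six pyrimidine
    mutation spectra, the 96 trinucleotide mutation signatures, and
    gene-level log2 copy-number ratios) from MAF-style variant tables and
    SEG or gene-level copy-number input, reduces it with supervised
    L1-based feature selection (extra-trees importance, LASSO, and an
    L1-penalized squared-hinge linear classifier), classifies cancer type
    with a soft-voting ensemble of a multilayer perceptron and a random
    forest, and evaluates the pipeline with nested 10-fold
    cross-validation, per-class metrics, feature-group ablation, and
    pairwise classifier-agreement analysis. A seeded synthetic-cohort
    simulator with planted type-specific drivers, signature contexts, and
    copy-number shifts makes every stage testable without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    S4Vectors,
    IRanges,
    GenomicRanges,
    SummarizedExperiment,
    Biostrings,
    glmnet,
    ranger,
    e1071,
    caret,
    withr,
    jsonlite
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
Collate: 
    'AllClasses.R'
    'AllGenerics.R'
    'OncoVote-package.R'
    'accessors.R'
    'classification.R'
    'cohort-io.R'
    'feature-selection.R'
    'evaluation.R'
    'feature-construction.R'
    'synthetic-cohort.R'
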