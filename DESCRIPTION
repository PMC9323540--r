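Package: ilqspr
Title: QSPR Models for Gas-Ionic-Liquid Partition Coefficients
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Quantitative structure-property relationship (QSPR) modelling of
    gas-ionic-liquid partition coefficients (log K) from 2D molecular
    descriptors of the ionic liquid's cation. Implements the full pipeline:
    descriptor-matrix pruning and standardization, deterministic stratified
    10-fold partitioning, sparse linear model building by orthogonal matching
    pursuit with an expulsion search, support vector regression and Gaussian
    process regression with greedy-substitution descriptor selection,
    cross-validated scoring (r-squared, RMSE, Lin's concordance correlation),
    permutation importance, and influence/applicability-domain diagnostics
    (leverage, standardized residuals, Cook's distance). A synthetic-data
    generator with planted sparse signals supports testing every stage
    without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    methods,
    stats,
    utils,
    tools,
    e1071,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    kernlab,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
Collate: 
    'AllClasses.R'
    'AllGenerics.R'
    'dataio.R'
    'diagnostics.R'
    'evaluation.R'
    'gpr.R'
    'mlr.R'
    'pipeline.R'
    'selection.R'
    'svr.R'
    'synthetic.R'
    'utils.R'
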