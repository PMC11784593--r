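Package: mscolor
Title: Multi-Stage Mixed-Effects Collaborative Longitudinal Regression
    for Imaging Genetics
Version: 0.99.0
Authors@R: person("Package", "Author", email = "author@example.com",
    role = c("aut", "cre"))
Description: Joint modeling of staged disease-progression trajectories from
    longitudinal neuroimaging quantitative traits (QTs) and sparse
    identification of the genetic variants that drive them. Implements
    MSColoR, a sparse multi-stage multi-task mixed-effects collaborative
    longitudinal regression: each disease stage carries its own genetic
    intercept and slope effect matrices, population aging effects are shared
    across stages, whole rows of SNP effects are selected jointly across
    tasks through an l-infinity,1 penalty solved by alternating closed-form
    reweighted updates, and per-SNP marginal effect sizes from large
    genome-wide association studies (GWAS) are integrated through a
    reference-panel linkage-disequilibrium matrix to borrow power from
    cohorts far larger than the imaging sample. Also provides three
    comparison methods (sparse multi-task regression and one-stage /
    multi-stage mixed-effects longitudinal baselines), a synthetic
    multi-stage cohort simulator with a paired GWAS cohort and reference
    panel, and an evaluation harness with nested cross-validation,
    SNP-selection scoring against simulated ground truth, and
    stage-contrast statistics.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    optparse,
    jsonlite,
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Collate: 
    'AllClasses.R'
    'AllGenerics.R'
    'accessors.R'
    'baselines.R'
    'cli.R'
    'constructors.R'
    'evaluation.R'
    'gwas.R'
    'io.R'
    'mscolor-package.R'
    'norms.R'
    'solver.R'
    'standardize.R'
    'synthetic.R'
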