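Package: nvcoupler
Title: Neurovascular Coupling Analysis of Functional Brain Networks
Version: 0.99.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Quantifies neurovascular coupling (NVC) from regional cerebral
    blood flow (CBF) and resting-state functional connectomes. Builds
    per-subject binary brain networks across a sparsity sweep, computes nodal
    degree, efficiency and betweenness centrality with area-under-curve
    integration over thresholds, and derives the NVC biomarkers: per-subject
    global CBF-topology Spearman coupling coefficients and per-region
    CBF/topology coupling ratios. Includes nonparametric group comparison
    with Benjamini-Hochberg FDR control, cognition correlations with
    hematologic covariate adjustment, a four-way classification of what
    drives regional coupling changes, and a synthetic cohort generator with
    known ground truth for power and type-I-error calibration.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.2)
Imports:
    methods,
    stats,
    utils,
    tools,
    igraph,
    jsonlite,
    RNifti,
    S4Vectors,
    SummarizedExperiment
Suggests: testthat (>= 3.0.0), withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
Collate: 
    'AllClasses.R'
    'AllGenerics.R'
    'cohort-config.R'
    'coupling.R'
    'driving.R'
    'group-analysis.R'
    'io.R'
    'network.R'
    'nodal-metrics.R'
    'nvcoupler-package.R'
    'pipeline.R'
    'stats.R'
    'synthetic-cohort.R'
    'utils.R'
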