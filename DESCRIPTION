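Package: metidd
Title: CSF Metabolomics Modelling of CNS Inflammatory Demyelinating Diseases
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Analysis pipeline for GC-MS cerebrospinal fluid (CSF) metabolite
    profiles of inflammatory demyelinating diseases (multiple sclerosis,
    neuromyelitis optica spectrum disorder, idiopathic transverse myelitis).
    Implements sum-intensity normalization, group-wise occurrence filtering
    and autoscaling; Student t-test contrasts with fold changes; NIPALS
    PLS-DA and OPLS-DA with cross-validated R2Y/Q2, variable importance in
    the projection (VIP) and p(corr); VIP-driven biomarker-panel construction
    evaluated by one-vs-rest ROC with bootstrap confidence intervals,
    optionally joined with clinical covariates (EDSS, oligoclonal bands, CSF
    protein); shared-and-unique-structures (SUS) screening of remission to
    relapse metabolite gradients with K-means confirmation; and Tanimoto
    chemical-similarity network construction with reaction-pair overlay, SIF
    export, hypergeometric pathway over-representation and betweenness-based
    pathway impact. A synthetic-cohort generator reproduces the statistical
    structure the analysis assumes so every stage is testable without
    external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    igraph,
    jsonlite,
    yaml,
    rlang
Suggests:
    testthat (>= 3.0.0),
    withr,
    pROC,
    mixOmics
Config/testthat/edition: 3
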