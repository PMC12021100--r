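Package: stratomics
Title: Multi-Omics Patient Stratification, Driver Inference and Network
    Analysis for Cohort Studies
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: An integrated computational chain for stratifying clinical
    cohorts from multi-layer omics data (transcriptomics, proteomics,
    metabolomics). Implements similarity network fusion with spectral
    clustering and eigengap/rotation-cost model selection, moderated
    linear-model differential abundance with covariate adjustment,
    shadow-feature consensus selection with random-forest importance,
    consensus Gaussian Bayesian-network structure learning with
    BIC-drop driver scoring, resampled Spearman consensus association
    networks with Leiden communities and senescence-marker overlays,
    and context-constrained flux balance analysis on a packaged toy
    stoichiometric model. Includes a synthetic cohort generator with
    ground truth so every stage is testable without restricted data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    methods,
    stats,
    utils,
    tools,
    igraph,
    ranger,
    mclust,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    limma,
    optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
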