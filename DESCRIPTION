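Package: effortpath
Title: Effort-Based Decision Modelling and Neurometabolic Path Analysis
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Simulation and analysis chain linking a metabolic signal
    (lactate) to physical effort-based decision-making at the
    inter-individual level. Implements a factorial effort-based decision
    task, a softmax choice model with within-block fatigue and learning
    states, MAP model inversion with Laplace evidence and parameter-recovery
    simulations, a synthetic cohort generator with a configurable
    standardized causal chain, between-subject statistics (outlier and
    inclusion filters, Pearson correlations, Steiger tests for dependent
    overlapping correlations), mediation and recursive path models, and
    voxel-mask overlap utilities for spectroscopy/fMRI co-localization.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    jsonlite,
    RNifti,
    stats,
    utils,
    withr
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
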