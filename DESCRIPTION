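Package: fingermet
Title: Metabolic Fingerprint Diagnostics from Plasma LDI Mass Spectra
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Simulation and analysis of plasma laser desorption/ionization
    mass-spectrometry (LDI-MS) metabolic fingerprints in the low-mass window
    (100-400 Da). Provides a synthetic-cohort generator with known
    differential metabolites, spectral preprocessing (baseline removal,
    smoothing, peak detection, m/z alignment, total-ion-current
    normalization, similarity and replicate-CV quality control), sparse
    (L1-penalized logistic) diagnostic modelling with cross-validated AUC,
    bootstrap confidence intervals, operating points and permutation tests,
    a four-criterion biomarker screen (selection frequency, rank-sum p,
    abundance, single-feature AUC), cation-adduct annotation at ppm
    tolerance with hypergeometric pathway over-representation, and
    pilot-based power/sample-size estimation under false discovery rate
    control. Includes a Bragg-spacing utility for low-angle X-ray
    diffraction peaks.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    glmnet,
    jsonlite,
    signal,
    stats,
    utils
Suggests:
    mzR,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
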