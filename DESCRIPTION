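Package: bilatdot
Title: Machine Learning Classification of Bilateral Diffuse Optical
    Transillumination Time Series
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for classifying breast-cancer status from bilateral
    continuous-wave diffuse optical transillumination time series. Implements
    per-measurement normalizations (relative change, z-score, zero centering,
    robust), spatio-temporal feature pooling (raw vectorization, temporal and
    spatial standard deviations, their concatenation, and six scalar
    heterogeneity biomarkers), enumeration and early fusion of candidate data
    representations, bilateral Euclidean-distance features that exploit the
    anatomical symmetry of the breasts, linear support-vector-machine model
    selection under a stratified shuffle-split protocol, ROC/AUC evaluation,
    and an optode-grid subsampling ablation. A synthetic-cohort generator with
    shared low-frequency vasomotion rhythms, wide channel-gain dynamic range,
    and a unilateral tumor effect makes the whole pipeline testable without
    clinical data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    data.table,
    e1071,
    jsonlite,
    stats,
    utils,
    graphics
Suggests:
    pROC,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
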