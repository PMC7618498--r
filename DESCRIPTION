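Package: SaccadeFlow
Title: Saccade Kinematics and Calcium-Imaging Encoding Analysis for Larval Zebrafish
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Detection, classification and kinematic analysis of conjugate and
    convergent saccades from binocular eye-position traces, together with an
    encoding analysis for simultaneously recorded two-photon calcium imaging:
    saccade-triggered d-prime with a permutation null, a 33-regressor design
    matrix convolved with a calcium impulse response function, cross-validated
    ridge regression with circular-permutation unique-variance attribution, and
    per-ROI oculomotor tuning metrics (saccade-type index, rectilinear
    eye-position fits, OKR power, PC1 score). Includes a synthetic-session
    generator with recorded ground truth so the full pipeline is testable
    end-to-end, and pre/post-manipulation behavioural deficit metrics.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.2)
Imports:
    methods,
    stats,
    utils,
    MASS,
    minpack.lm,
    signal,
    jsonlite,
    S4Vectors,
    SummarizedExperiment
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
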