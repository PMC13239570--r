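Package: trackrel
Title: Reliability Assessment of Markerless Lung-Tumor Tracking on
    Single- and Dual-Energy Fluoroscopy
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Simulates fast-kV-switching thoracic fluoroscopy with known
    tumor trajectories, generates bone-suppressed dual-energy images by
    weighted logarithmic subtraction, tracks the tumor by masked
    normalized cross-correlation with a peak-to-sidelobe-ratio
    confidence, estimates ground truth with a constant-acceleration
    Kalman filter, stratifies datasets by tracking success rate, and
    fits a domain-adapted, sample-weighted, regularized logistic model
    that classifies each tracked frame as reliable or unreliable at a
    95-percent-specificity operating point.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    Rcpp,
    jsonlite,
    stats,
    tiff,
    utils
LinkingTo: Rcpp
Suggests:
    glmnet,
    pROC,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
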