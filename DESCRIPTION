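Package: biopsim
Title: Patient-Level Evaluation of Prostate Cancer Heatmaps by Simulated Targeted Biopsies
Version: 0.1.0
Authors@R: person("Package", "Maintainer", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Evaluates 3D lesion-probability heatmaps for clinically significant
    prostate cancer (csPCa) at the patient level by simulating targeted
    transperineal biopsies. Predicted lesions are extracted from the heatmap by
    thresholding and 3D connected-component labeling, filtered at 0.07 cc, and
    the two largest are biopsied with a straight needle modeled as a point on
    the transverse plane; the per-biopsy hit probability is the overlap of the
    predicted and reference lesion footprints on that plane. Patient-level
    TP/FP/TN/FN calls at ISUP grade-group thresholds feed sensitivity,
    specificity, PPV and NPV with binomial confidence intervals. A seeded
    synthetic-cohort generator (ellipsoid prostate phantoms, graded reference
    lesions, heatmaps with controllable fidelity) makes the whole pipeline
    testable without images or a trained model. Includes minimal NIfTI-1 I/O.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    jsonlite,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
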