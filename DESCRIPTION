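Package: opgpredict
Title: Longitudinal MRI Features and Progression Prediction for Optic Pathway Glioma
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for studying radiographic and visual progression of
    optic pathway glioma (OPG) from longitudinal multi-modal MRI. Provides
    a synthetic cohort generator with known ground truth (tubular
    optic-nerve masks, streamline-defined optic radiations, group-dependent
    scaled fractional-anisotropy signal), optic-nerve morphometry (volume,
    boundary-walk perimeter, centerline thickness, tortuosity index),
    ROI-logic streamline filtering, per-region intensity feature extraction
    with linear histogram matching, static and dynamic (delta) feature
    tables, and a linear support vector machine with sequential forward
    feature selection evaluated under paired leave-two-out
    cross-validation, with confusion metrics, ROC/AUC analysis and
    univariate feature ranking.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    e1071,
    jsonlite,
    RNifti,
    stats,
    tools,
    utils
Suggests:
    optparse,
    pROC,
    withr,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
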