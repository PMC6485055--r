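Package: palsymetry
Title: Objective Facial Palsy Evaluation from Facial Symmetry Features
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for objective evaluation and classification of facial
    paralysis from frontal still images of four facial expressions. Provides a
    synthetic face and eye generator with analytic ground truth, shape-indexed
    cascaded-regression facial landmarking (68-point scheme) with HOG and
    sliding-window machinery, iris segmentation by Daugman's
    integro-differential operator with parabolic upper-eyelid occlusion
    modelling, eleven left/right symmetry ratio features, and a two-stage
    hybrid rule + regularized-logistic-regression classifier separating
    healthy from palsy subjects and peripheral from central palsy, with
    cross-validated model selection and ROC/AUC evaluation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    glmnet,
    jsonlite,
    png,
    purrr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils
Suggests:
    EBImage,
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
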