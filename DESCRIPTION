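Package: tsfs
Title: Teacher-Student Distillation Feature Selection for Functional
    Connectivity Classification
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Three-stage feature selection for two-class classification of
    resting-state functional connectivity: a deep "teacher" network is
    trained to classify subjects from the upper-triangle Pearson
    connectivity features and a low-dimensional code layer is extracted; a
    one-hidden-layer "student" network is distilled to reproduce the
    standardized codes, and the squared row norms of its input weight
    matrix, diag(W W'), rank the connectivity features; a cumulative
    sequential forward scan over the ranked features selects the prefix
    maximizing cross-validated accuracy. Includes a synthetic cohort
    generator with planted class-discriminative region-pair correlations,
    stratified k-fold and site-wise evaluation (accuracy, sensitivity,
    specificity), and anatomical reporting of selected region pairs
    (lobe and hemisphere count tables, BrainNet Viewer node/edge export).
License: MIT
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    MASS,
    e1071,
    glmnet,
    randomForest,
    rpart,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
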