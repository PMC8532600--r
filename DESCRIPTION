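Package: cowaccel
Title: Posture and Behavior Classification from a Flank-Mounted Triaxial
    Accelerometer in Dairy Cows
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for turning 5 Hz triaxial acceleration logs from a
    sensor on a dairy cow's left flank into posture (standing, left/right
    sternal recumbency) and behavior (feeding, moving, resting, ruminating,
    standing still) predictions. Provides sensor CSV and annotation-interval
    input/output with removal of non-univocal observations, a synthetic
    signal generator with posture-dependent gravity orientation and
    behavior-dependent dynamics, fixed-length overlapping window
    segmentation, a 36-statistic window feature set, correlation-based
    feature pruning, four classifier backends (random forest, k-nearest
    neighbors, gradient boosting, support vector machine), and a complete
    multi-class assessment panel (accuracy with exact binomial confidence
    interval and no-information-rate test, Cohen's kappa, per-class
    sensitivity, specificity, precision, negative predictive value,
    prevalence, and balanced accuracy), together with the published
    confusion matrices of the motivating study as fixtures.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    class,
    dplyr,
    e1071,
    randomForest,
    stats,
    tibble,
    utils,
    xgboost,
    yaml
Suggests:
    caret,
    jsonlite,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
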