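Package: icscore
Title: Interval Coded Scoring Systems for Binary Classification
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Learns sparse, integer-point, interval-based clinical scoring
    systems from binary-labelled tabular data. Variables are discretised
    into intervals via training-sample percentiles and expanded to binary
    indicators; interval weights are then estimated either by a linear
    program with a total-variation (fused) penalty on adjacent-interval
    weight differences (lpICS) or by a constrained elastic net on a
    cumulative encoding (enICS). Iterative reweighting drives the model
    towards piecewise-constant, few-variable solutions; weights are scaled
    and rounded to integer points, adjacent equal-point intervals are
    merged, and a logistic recalibration maps total scores to risks.
    Includes cross-validated semi-automatic complexity tuning, an
    effect-preselection screen, ROC/AUC, accuracy and calibration-curve
    assessment, score-card rendering, and a synthetic-data generator with
    known interval-score structure.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Matrix,
    methods,
    stats,
    utils,
    grDevices,
    jsonlite,
    glmnet,
    e1071,
    yaml,
    Rcpp
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    pROC,
    withr
Config/testthat/edition: 3
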