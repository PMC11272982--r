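Package: cardiofuse
Title: Cardiovascular Risk Prediction with Boosted Decision Fusion and
    Swarm-Based Feature Selection
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: An end-to-end pipeline for clinical tabular risk prediction in
    the style of the classic heart-disease cohorts: chained-equation (MICE)
    imputation of missing values, label encoding and standard scaling,
    interquartile-range outlier capping, SMOTE minority oversampling with an
    imbalance-ratio trigger, a two-tier feature selector that couples a
    grasshopper-swarm subset search with ridge-coefficient re-scoring, an
    AdaBoost decision-fusion classifier, an exhaustive ("babysitting") grid
    tuner with a per-trial ledger, and the usual classification metrics
    (accuracy, precision, recall, F1, trapezoidal AUC). A synthetic-data
    generator with a planted informative feature subset, controllable
    missingness, outliers and class imbalance makes every stage testable
    without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    optparse,
    rpart,
    knitr,
    rmarkdown
VignetteBuilder: knitr
Config/testthat/edition: 3
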