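Package: tmlearn
Title: Transformational Machine Learning for Collections of Related Regression Tasks
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.com",
    role = c("aut", "cre"))
Description: Multi-task meta-learning by representation transformation. Given a
    collection of regression tasks that share one intrinsic feature schema
    (for example QSAR tasks over a common molecular fingerprint), per-task
    baseline models are trained and every example is re-represented by the
    predictions of the models learned on the other tasks (the extrinsic, or
    transformed, representation). Models trained on this representation can be
    stacked with the baseline models via nonnegative least squares or ridge
    regression. Includes the full evaluation protocol (per-task cross-validated
    RMSE, paired sign and Wilcoxon signed-rank tests), interpretation tools
    (attribute-model importance rankings, prediction-profile hierarchical
    clustering of examples and tasks with Newick export), a synthetic
    related-task benchmark generator, and an end-to-end pipeline driver.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite,
    yaml,
    withr,
    pracma,
    ranger,
    xgboost,
    e1071,
    caret,
    nnet,
    ape
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
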