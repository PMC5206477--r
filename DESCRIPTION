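Package: exprdose
Title: Predicting Clinical Dose from Gene Expression with Trees, Support
    Vector Regression and Ensembles
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Tools for predicting a continuous clinical dose or
    concentration from microarray gene-expression profiles. Implements
    iterative sure independence screening (marginal correlation screening
    alternated with lasso selection on residuals) with a
    multicollinearity and coefficient-significance post-filter;
    from-scratch CART-style regression trees and epsilon-insensitive
    support vector regression (linear and polynomial kernels, SMO dual
    solver); bootstrap aggregation and squared-loss gradient boosting of
    trees; a repeated 70/30 holdout benchmarking harness with RMSE, MAD
    and R-squared metrics and cross-validated hyperparameter tuning; a
    multivariate-normal synthetic data generator driven by dose-gene
    correlation structure; and a Monte-Carlo training-set-size sweep that
    locates the sample size at which bagged trees start to outperform a
    single tree.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    graphics,
    grDevices,
    glmnet,
    jsonlite,
    yaml,
    data.table
Suggests:
    testthat (>= 3.0.0),
    e1071,
    kernlab
Config/testthat/edition: 3
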