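Package: gwpred
Title: Genome-Wide Prediction with Penalized Regression and Honest Model Evaluation
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for genome-wide prediction of quantitative traits from SNP
    markers: ridge regression, the LASSO and the adaptive LASSO fitted by
    coordinate descent over regularization paths, together with the competing
    hold-out evaluation statistics (test mean squared error, squared Pearson
    correlation, coefficient of determination) and their covariance/variance
    decomposition. Includes a pedigree-based quantitative-trait simulator with
    epistasis, genomic imprinting and dominance for end-to-end testing, and a
    pipeline that reproduces the model-comparison experiment in which the
    squared Pearson correlation selects a different "best" model than the test
    mean squared error.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    dplyr,
    generics,
    ggplot2,
    purrr,
    Rcpp,
    rlang,
    stats,
    tibble,
    tidyr,
    utils
LinkingTo: Rcpp
Suggests:
    glmnet,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
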