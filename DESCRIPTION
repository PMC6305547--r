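Package: hofcn
Title: High-Order Functional Connectivity Networks with Sparsity and
    Modularity Priors
Version: 0.1.0
Authors@R:
    person("hofcn", "maintainers", email = "hofcn@example.org",
           role = c("aut", "cre"))
Description: Estimation of high-order functional connectivity networks
    (HoFCN) from regional fMRI time series.  Low-order networks are
    computed by Pearson correlation or sparse representation inside
    sliding windows; an initial high-order network is obtained by a
    matrix-variate normal maximum-likelihood fixed point over the
    windowed network sequence, and is then refined by a proximal
    gradient scheme combining soft-thresholding (sparsity prior) and
    singular-value thresholding (modularity prior).  Includes a nested
    leave-one-out cross-validation harness (t-test feature selection,
    linear support vector machine) for two-group classification, a
    seeded synthetic-data generator, and a command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    jsonlite,
    Rcpp,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    glmnet,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
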