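Package: rbfspls
Title: Radial Basis Function Sparse Partial Least Squares for Image Regression
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Sparse partial least squares (sPLS) regression in PLS-SVD form for
    relating a moderate number of covariates to very high dimensional image
    responses, preceded by a radial B-spline basis expansion that reduces each
    co-registered image volume to a vector of knot coefficients. Provides the
    soft-thresholded NIPALS inner loop with asymmetric deflation, the Q-squared
    cross-validation criterion with grid search over the two L1 penalties and
    the number of components, back-projection of sparse basis loadings to
    coefficient images, a simulation engine with Kronecker-structured loadings
    and binary cross-shaped true images for benchmarking variable selection
    (sensitivity, specificity, c-index, probability images), and ingestion of
    masked NIfTI volumes plus covariate tables for real morphometry studies.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
Imports:
    Matrix,
    RNifti,
    dplyr,
    generics,
    ggplot2,
    png,
    rlang,
    stats,
    tibble,
    utils,
    yaml
Suggests:
    mixOmics,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
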