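Package: flimglia
Title: Label-Free Microglia Detection from NAD(P)H Fluorescence Lifetime Imaging
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for detecting microglia in label-free NAD(P)H fluorescence
    lifetime imaging (FLIM) data. Implements time-correlated single photon
    counting (TCSPC) decay modelling with instrument-response-function
    convolution, per-pixel two-component exponential Levenberg-Marquardt
    fitting, construction of labeled training instances from fitted lifetime
    parameters (fitting-based method, FBM) or raw 256-bin decay histograms
    (decay-based method, DBM), a one-hidden-layer feed-forward network trained
    by Levenberg-Marquardt steps with Bayesian regularization, threshold
    calibration by overlap maximization, and overlap-based detection metrics
    (TPR, PPV, FNR, FDR). Includes a synthetic FLIM phantom generator with
    ground-truth masks so the whole pipeline can be exercised without
    microscope data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    Rcpp,
    rlang,
    stats,
    tibble,
    tidyr,
    tiff,
    utils,
    withr
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    EBImage,
    minpack.lm,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
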