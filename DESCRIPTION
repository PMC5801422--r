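Package: rhythmboot
Title: Bootstrap-Robust Rhythmicity Measures for Time-Course Expression Data
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Detection of rhythmic (oscillatory) genes in long-series
    time-course expression data in a way that is robust to the choice of
    probe-level normalization method. Provides a per-gene two-way median
    polish decomposition of background-corrected probe intensities, a
    parametric residual bootstrap that regenerates probe-level datasets
    centered at the fitted signal, pluggable normalization (quantile,
    constant, cyclic loess, invariant set) and rhythmicity detectors
    (cosinor F-test, rank-template test, external p-values), the standard
    measure M = 1 - BH-adjusted p-value and its bootstrap-stabilized
    counterpart M_Robust = E-hat - RMSE-hat, plus cross-normalization
    correlation and concordance reporting and a synthetic data generator
    with known ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    limma,
    jsonlite,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse,
    yaml
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
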