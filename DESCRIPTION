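Package: tremorkit
Title: Kinetic Tremor Quantification from Digitizing-Tablet Circle Drawings
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Quantifies kinetic tremor from pen trajectories recorded on a
    digitizing tablet during a circle-drawing task. Implements a spectral
    tremor statistic computed from short-time Fourier segments after removal
    of a fitted 1/f^alpha background, multiscale sample entropy of the
    transverse drawing velocity, echo-state-network (reservoir) feature
    extraction with Lyapunov-exponent tuning and memory-capacity estimation,
    and LASSO score models and model ensembles that map the extracted
    features to continuous tremor severity scores. A synthetic drawing
    generator emulating intermittent 4-9 Hz tremor supports calibration and
    end-to-end testing without clinical data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    signal,
    glmnet,
    Rcpp,
    yaml,
    jsonlite
LinkingTo: Rcpp, RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
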