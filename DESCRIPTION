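Package: nlrm2
Title: Nonlinear Magnetic Response Quantification of Nanoparticle-Labeled Cells
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Forward modelling and inversion of the longitudinal nonlinear
    magnetic response (second harmonic of magnetization, M2) of polydisperse
    superparamagnetic nanoparticle ensembles, and its use for counting
    nanoparticle-labeled mesenchymal stem cells in tissue specimens. Includes
    a harmonic-balance solver for the axially symmetric Brown rotational
    Fokker-Planck equation, quasi-static analytic and Fourier oracles, field
    sweep preprocessing (branch averaging, antisymmetrization, hysteresis
    screening), nonlinear least-squares inversion of sweep curves into
    ensemble magnetic parameters, conversion of fitted magnetics into
    per-gram counts of magnetically active centers and labeled cells, and a
    synthetic sweep generator with known ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    deSolve,
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    minpack.lm,
    pracma,
    Rcpp,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    yaml
LinkingTo: Rcpp, RcppArmadillo
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
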