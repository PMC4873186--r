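Package: stereobem
Title: Binocular Energy Model Simulations of Depth Perception in
    Mixed-Correlation Random-Dot Stereograms
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Procedural generation of static, dynamic and
    alternating-correlation random-dot stereograms, binocular energy model
    (BEM) complex cells with quadrature Gabor subunits, biphasic temporal
    kernels and a squaring output nonlinearity, and a noisy opponent
    population readout for simulated near/far psychophysics.  Includes the
    accompanying statistics: normalized half-matched response, fractional
    area of psychometric functions, exact binomial confidence intervals and
    a Monte-Carlo dispersion test for binomial proportions.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    stats,
    graphics,
    grDevices,
    utils,
    yaml,
    jsonlite,
    png
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
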