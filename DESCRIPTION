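Package: thalamr
Title: Multi-Scale Models of Thalamic State-Dependent Responsiveness
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Conductance-based adaptive exponential integrate-and-fire (AdEx)
    simulations of thalamocortical relay (TC) and reticular (RE) neurons and
    their recurrent network, together with a second-order mean-field model
    built on a semi-analytic transfer function with an effective firing
    threshold. Ships awake/sleep/spindle parameter presets, stimulus and
    Ornstein-Uhlenbeck noise generators, the two-stage transfer-function
    fitting pipeline, and a battery of responsiveness protocols
    (stimulus-shape scans, gain versus cortical drive, synaptic-noise scans,
    burst/tonic classification, spindle oscillation and bifurcation analyses).
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Rcpp,
    tibble,
    dplyr,
    tidyr,
    purrr,
    rlang,
    ggplot2,
    graphics,
    stats,
    utils,
    minpack.lm,
    generics,
    jsonlite
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    optparse,
    withr,
    knitr,
    rmarkdown
VignetteBuilder: knitr
Config/testthat/edition: 3
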