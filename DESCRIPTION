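Package: isletsim
Title: Population Model of Pancreatic Insulin Secretion by Heterogeneous Firing Units
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Simulates whole-organ pancreatic insulin secretion as a large
    population of independent, heterogeneous, threshold-firing secretory
    units with refractory recovery and glucose-driven potentiation.  The
    unit population is coupled either to a closed-loop in vivo
    glucose-insulin environment (liver chain, plasma insulin kinetics,
    stochastic hepatic glucose output, gut absorption, exogenous infusions)
    or to an open-loop perfused-pancreas in vitro environment.  Includes
    fitting of the firing-threshold distribution from percent-activation
    data, builders for classical perfusion, enteral-feeding, sinusoidal,
    pulsed and IVGTT glucose protocols, diabetes phenotype scenarios, and
    post-processing tools for pulse detection, period estimation and
    entrainment metrics.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    dplyr,
    tibble,
    tidyr,
    rlang,
    ggplot2,
    generics,
    jsonlite,
    yaml,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
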