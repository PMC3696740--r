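Package: multistable
Title: Competitive Network Models of Perceptual Multistability with
    Short-Term Synaptic Depression
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Simulation and closed-form analysis of competitive neural
    network models of perceptual rivalry. Implements a stochastic ring
    neural field on the orientation domain with short-term synaptic
    depression, space-free two- and three-population mutual-inhibition
    networks, fast-slow (adiabatic) dominance-time theory for the
    depression-driven oscillations, dominance-epoch extraction from
    simulated trajectories, exponential and three-point gamma fits to
    dominance-time distributions, and the contrast-inference probability
    that an observer sampling dominance times assigns to one stimulus
    being stronger than the other. Stochastic integration uses the
    Euler-Maruyama scheme with spatially correlated noise on the ring.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    dplyr,
    generics,
    ggplot2,
    graphics,
    jsonlite,
    purrr,
    Rcpp,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils
LinkingTo:
    Rcpp
Suggests:
    knitr,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
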