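Package: coevotrade
Title: Stochastic Predator-Prey Coevolution with Dynamical Growth-Defense
    Trade-Offs
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Individual-based stochastic modelling of predator-prey
    coevolution with de novo mutations in both species. An exact
    Gillespie (direct method) engine simulates birth, death, resource
    competition and predation reactions over a dynamic set of prey and
    predator types, where the prey growth-defense trade-off emerges from
    a power-law predation function and changes shape as the predator
    coevolves. Includes ensemble analyses of coexistence, type richness
    and Shannon diversity, a phase-lag estimator for population cycles,
    and nonlinear least-squares fitting of power-law trade-off curves to
    growth-assay data with cheap/costly shape classification.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    stats,
    graphics,
    grDevices,
    utils,
    yaml,
    minpack.lm
LinkingTo:
    Rcpp
Suggests:
    testthat (>= 3.0.0),
    deSolve,
    jsonlite,
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
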