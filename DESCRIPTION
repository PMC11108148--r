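Package: edneguq
Title: Uncertainty Quantification and Sensitivity Analysis for an
    Electrodiffusive Neuron-Extracellular-Glia Model
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Forward simulation and variance-based global sensitivity
    analysis of a six-compartment electrodiffusive neuron-extracellular-glia
    (edNEG) model. The model tracks ion amounts (Na+, K+, Ca2+, Cl-),
    Hodgkin-Huxley gating variables and compartment volumes (34 stiff ODEs),
    with electrical potentials obtained from an algebraic
    Kirchhoff-Nernst-Planck solve. Includes implicit Radau integration with
    an exact Jacobian, spike-feature extraction (spike counts, firing
    frequency, first-spike latency, depolarization-block onset), uniform
    parameter priors, Saltelli designs, polynomial chaos surrogates by point
    collocation, and first-order, total-order, grouped, time-resolved,
    weighted and generalized Sobol' indices, together with analytic
    benchmark functions for validating every estimator.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Rcpp,
    deSolve,
    lhs,
    jsonlite,
    stats,
    utils
LinkingTo: Rcpp
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
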