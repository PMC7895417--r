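Package: clonecon
Title: Building and Checking Clone-Consistent Ecosystem Models
Version: 0.1.0
Authors@R:
    person("Package", "Maintainer", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Tools for population models of ecological communities that are
    invariant under splitting or merging populations of identical individuals
    (clone consistency). Provides an algebra of impact functions built from
    linear combinations of transformed parameters and abundances, a numerical
    checker that falsifies clone consistency of arbitrary black-box model
    terms, adaptive Runge-Kutta simulation of population dynamics of the form
    dx_j/dt = x_j * phi_j(x, a), a zoo of concrete community models
    (generalized Lotka-Volterra, logarithmic predator-prey, pollination and
    grazing, sparse product-form ensembles), and a full case study on
    pairwise-interaction models for polymicrobial urinary-tract-infection
    communities, including a synthetic conditioned-medium experiment generator
    and end-to-end parameter recovery.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
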