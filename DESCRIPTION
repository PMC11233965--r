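Package: imprintr
Title: Filial Imprinting Dynamics, Color Generalization, and Avian Color Space
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Models of spontaneous color generalization in newly hatched
    chicks: a multiplicative preference-update model of filial imprinting with
    Gaussian update weights, an unbiased generalization null model based on
    Shepard's universal law, a Bayesian ideal-observer account of color
    predispositions, avian tetrahedral color-space computation from
    reflectance spectra, and a behavioral analysis pipeline from markerless
    tracking output to generalization curves with chance-level tests.
    Includes seeded synthetic-data generators reproducing the experimental
    designs (imprinting sessions, generalization tests, predisposition tests)
    with known ground truth, so every analysis step is testable end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    pracma,
    purrr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    withr
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
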