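Package: edesprot
Title: Postprandial Glucose-Insulin Dynamics with Amino Acid Effects
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.com",
           role = c("aut", "cre"))
Description: Simulation and calibration of a physiology-based ordinary
    differential equation model of postprandial glucose and insulin
    dynamics extended with plasma amino acid (AA) effects on hepatic
    glucose production and pancreatic insulin secretion (the E-DES-PROT
    model). Plasma AA concentrations enter as a shape-preserving cubic
    Hermite forcing function. The package provides weighted multi-start
    least-squares calibration of meal-challenge time series, AIC/BIC
    model comparison against the base E-DES model, profile-likelihood
    identifiability analysis, metabolite flux decomposition, and a
    synthetic meal-challenge generator for end-to-end testing.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    deSolve,
    minpack.lm,
    jsonlite,
    yaml,
    pracma,
    stats,
    utils
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
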