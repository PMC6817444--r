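Package: adcpk
Title: Pharmacokinetics, Biodistribution and Efficacy Analysis for
    Antibody-Drug Conjugate Predose Studies
Version: 0.1.0
Authors@R:
    person("Package", "Author", , "author@example.com", role = c("aut", "cre"))
Description: Tools for preclinical antibody-drug conjugate (ADC) studies
    in which unconjugated parental antibody is predosed to saturate
    target-mediated uptake in normal tissues. Implements a two-compartment
    antibody pharmacokinetic model with parallel linear and saturable
    (Michaelis-Menten) clearance, proportional-error weighted least-squares
    parameter estimation from multi-dose concentration data, simulation of
    predose + ADC regimens with assay-specific readouts (total antibody
    versus conjugated ADC), conversion of gamma-counting tissue data to
    decay-corrected percent injected dose per gram, tumor-growth-inhibition
    summaries from caliper measurements, and seeded synthetic-data
    generators for every pipeline stage.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    deSolve,
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    MASS,
    minpack.lm,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
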