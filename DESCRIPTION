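Package: bicompete
Title: Simulation and Inference for Diatom-Dinoflagellate Competition
    Experiments
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Tools for semi-continuous bi-algal competition experiments
    between a diatom and a dinoflagellate. Simulates batch and
    semi-continuous (daily dilution) culture dynamics under a two-species
    Lotka-Volterra model, infers monoculture growth parameters and the
    interspecific interaction coefficients alpha and beta from daily
    cell-density time series, computes elemental stoichiometry (POC/PON,
    PON/POP) and lipid biomarker indices (16:1/16:0, EPA/DHA,
    brassicasterol/(brassicasterol + dinosterol)), and runs the study's
    statistical layer: fixed-effects GLMs with AICc model selection,
    univariate smoothing-spline additive models with GCV, and ordinary
    least-squares regressions. A synthetic-data generator emulates the
    full 3x3x3 factorial design (temperature x N:P supply ratio x
    nutrient level, triplicated) with hemocytometer counting noise so
    that every pipeline stage is testable without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    mgcv,
    minpack.lm,
    stats,
    utils,
    tools,
    jsonlite,
    yaml
LinkingTo:
    Rcpp
Suggests:
    deSolve,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
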