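Package: hydrodry
Title: Trait-Based Simulation of Plant Dehydration and Hydraulic Failure
    During Drought
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: A compartment soil-plant-atmosphere hydraulic model that
    predicts the dynamics of plant water potential from full hydration
    through stomatal closure to hydraulic failure (99% loss of leaf
    hydraulic conductivity). Includes pressure-volume and xylem
    vulnerability response curves, temperature-dependent residual
    (cuticular and bark) conductances, a drought-deciduous leaf-shedding
    response, pot-soil water retention, trait-extraction procedures for
    bench-dehydration and drought-box time series, dehydration-time
    metrics (time to stomatal closure, time from closure to hydraulic
    failure, and their sum), variance-based Sobol global sensitivity
    analysis of those metrics over trait perturbations, and a synthetic
    dry-down data generator for end-to-end testing.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    minpack.lm,
    stats,
    utils
LinkingTo:
    Rcpp
Suggests:
    jsonlite,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
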