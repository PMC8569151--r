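Package: aerialpheno
Title: Aerial High-Throughput Phenotyping of Peanut Canopy Traits from RGB Vegetation Indices
Version: 0.1.0
Authors@R:
    person("TAREC", "Phenomics", email = "phenomics@example.org", role = c("aut", "cre"))
Description: Pipeline for estimating peanut leaf area index (LAI) and lateral
    growth (LG) from UAV RGB orthomosaics: per-plot zonal extraction of digital
    numbers, panel-based exponential empirical-line calibration to reflectance,
    six RGB vegetation indices (BGI, RGR, NPPR, NGRDI, PPR, NCPI), frozen and
    refittable linear trait models (sum and product forms), AIC stepwise
    predictor selection, a small seeded multilayer perceptron, field-trial
    evaluation statistics (PRESS, AIC/BIC, Tukey HSD, validation error,
    trait-to-yield cubic regression), and a synthetic field-trial scene
    generator so every stage is testable without field data.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    stats,
    utils,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
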