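Package: respwolf
Title: Grey Wolf and Tasmanian Devil Metaheuristics for Respiratory
    Disease Classification
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Population-based, gradient-free optimization tools for
    clinical tabular classification. Implements the Tasmanian devil
    optimization (TDO) algorithm for continuous minimization and wrapper
    feature selection, a grey wolf optimizer (GWO) together with an
    improved variant (IGWO) using weighted leaders, a decaying Gaussian
    prey-estimate perturbation, a two-stage convergence schedule and a
    sine-cosine escape step, and a compact one-dimensional convolutional
    classifier whose weights are trained directly by IGWO. Includes
    missing-value imputation, feature encoding, stratified splitting,
    diagnostic performance metrics (sensitivity, specificity, predictive
    values, prevalence) with canonical and as-printed conventions, a
    synthetic four-group respiratory cohort generator emulating
    saliva-permittivity data, and an end-to-end pipeline with a benchmark
    harness for comparing optimizers.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    class,
    jsonlite,
    stats,
    utils,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
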