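Package: cpeopt
Title: Surrogate-Based Optimization of Cloud Point Extraction Processes
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for screening and optimizing cloud point extraction (CPE) of
    bioactive compounds (total phenolics, carotenoids, antioxidant activity)
    from plant by-products. Provides mixed categorical/continuous factor-space
    handling with one-hot encoding and min-max normalization, Plackett-Burman
    and one-variable-at-a-time (OVAT) designs, a multilayer-perceptron
    surrogate trained by multi-restart quasi-Newton (BFGS) minimization with
    topology search, Yoon connection-weight global sensitivity analysis, and
    mixed-variable NSGA-II-style multi-objective optimization returning a
    Pareto front and an equal-weights compromise optimum. A configurable
    response-surface simulator with phase-separation gating makes the whole
    pipeline testable without laboratory data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    graphics,
    utils,
    tools,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    knitr
Config/testthat/edition: 3
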