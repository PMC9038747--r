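Package: soanfis
Title: Seasons-Optimization Trained Neuro-Fuzzy Models for Irrigation
    Water-Use Efficiency and Yield
Version: 0.1.0
Authors@R:
    person("soanfis", "developers", email = "soanfis@example.org",
           role = c("aut", "cre"))
Description: Tools for estimating crop yield and water-use efficiency (WUE)
    from irrigation and climate features with a first-order Takagi-Sugeno
    fuzzy inference system whose Gaussian premise parameters are tuned by the
    Seasons Optimization (SO) population metaheuristic and whose linear
    consequents are solved by ridge-regularized least squares. Includes fuzzy
    c-means rule initialization, goodness-of-fit criteria (R2, RMSE, scatter
    index, relative absolute error, Nash-Sutcliffe-style efficiency),
    input-combination model selection, irrigation agronomy formulas (WUE,
    application efficiency, shaded-strip daily water requirement, coefficient
    of variation classes), a synthetic feature-table generator with a planted
    fuzzy surface for validation, packaged treatment fixture tables, CSV/JSON
    I/O and a command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    jsonlite,
    optparse,
    stats,
    tools,
    utils
Suggests:
    testthat (>= 3.0.0),
    yaml
Config/testthat/edition: 3
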