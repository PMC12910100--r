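Package: gradsamp
Title: Simulation-Based Optimization of Sampling Effort Allocation in
    Gradient Studies
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Simulates regression-type gradient studies to quantify the
    trade-off between the number of sampling locations along an
    environmental gradient and the number of replicates per location,
    under a fixed total sample budget. Provides six canonical response
    shapes (linear, hump, skewed hump, saturating, exponential,
    logistic), six location-placement strategies (systematic,
    log-systematic, random, and three preferential strategies weighted
    by local slope and/or response extremeness), a proportional
    Gaussian noise model, polynomial curve fitting with AIC-based order
    selection, and three prediction-accuracy metrics (multiple
    R-squared, through-origin prediction success, negative RMSE). A
    factorial simulation engine crosses shapes, strategies, sample-size
    factorizations, noise levels, a-priori-knowledge and
    gradient-length scenarios, and downstream tools analyze the
    resulting accuracy surface with linear mixed models, Nakagawa
    R-squared, variation partitioning, and per-case classification of
    replication effects.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    lme4,
    multcomp,
    stats,
    tools,
    utils,
    jsonlite,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
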