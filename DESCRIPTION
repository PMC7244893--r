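Package: aloccu
Title: Autologistic Multi-Season Occupancy Models for Camera-Trap Surveys
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: Fits dynamic (multi-season) site-occupancy models with an
    autologistic parameterization to detection/nondetection histories from
    camera-trap surveys. The latent occupancy chain is marginalized exactly
    with a two-state forward recursion, so the same likelihood supports both
    maximum-likelihood estimation and Bayesian inference via adaptive
    random-walk Metropolis MCMC. Includes Gelman-Rubin convergence
    diagnostics, posterior-predictive goodness of fit (Bayesian p-value),
    derived colonization/persistence and yearly mean-occupancy summaries via
    forward-filtering backward-sampling, a synthetic camera-trap survey
    generator for power analysis and testing, and a command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    yaml,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    optparse,
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
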