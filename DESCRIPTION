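Package: pleasuretrack
Title: Modelling Pleasure Ratings of Single and Multiple Images
Version: 0.1.0
Authors@R:
    person("Analysis", "Pipeline", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Tools for studying how observers report the pleasure of one
    image among four and the combined pleasure of four images rated on a
    1-9 key-press scale. Provides a canonical trial-level data model with
    delimited-text storage, a synthetic-observer simulator (latent image
    pleasures, condition-specific late noise, and a constant guess rate),
    a registry of deterministic rating models (faithful, averaging,
    average-biased, weighted-average, linear, and high-pleasure
    attenuation families), per-participant leave-one-out cross-validated
    fitting by box-constrained RMSE minimisation, cross-participant model
    comparison with winner counts, faithful-prediction error and rating
    variability analyses, k-means clustering of fitted linear-transform
    parameters, and a reproducible simulate-fit-analyse-report pipeline
    with a command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    grDevices,
    graphics,
    jsonlite,
    withr
Suggests:
    testthat (>= 3.0.0),
    optparse,
    yaml
Config/testthat/edition: 3
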