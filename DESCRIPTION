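Package: demotransit
Title: Movement Type and Child Mortality After Democratic Transitions
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for analysing whether the type of movement behind a democratic
    transition (protest-led versus violence-led) predicts lower- or
    higher-than-expected under-5 child mortality after the transition.
    Implements country-specific interrupted-time-series estimation of long-run
    mortality deviations from the pre-transition trend, bivariate and
    multivariate effect regressions with Monte-Carlo propagation of
    credible-interval uncertainty, multiverse (all-covariate-subset) robustness
    summaries including the Young-Holsteen robustness ratio, coarsened exact
    matching with stratum reweighting, and the Braumoeller-Goertz necessity
    test comparing a one-sided exact binomial lower bound on the deviant-case
    proportion to an assumed measurement-error rate. Ships a calibrated
    synthetic-data generator and the 51-country transition classification
    table, and a pipeline driver that runs every stage from one configuration.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    graphics,
    metafor,
    sandwich,
    lmtest,
    yaml
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    withr
Config/testthat/edition: 3
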