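Package: tcExcess
Title: Causal Estimation and Prediction of Tropical Cyclone Health Impacts
Version: 0.1.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Estimates county-level excess health events attributable to
    tropical cyclone exposures from panel data of event counts, using a
    Bayesian matrix-completion model with a negative binomial likelihood and
    a log link to impute counterfactual counts for storm-exposed counties.
    Provides the excess-event estimands built from the counterfactual
    posterior (individual excess events, excess rates per 100 000, storm and
    study totals), a modularized (cut-posterior) predictive stage relating
    excess rates to storm and community features with full uni-directional
    uncertainty propagation, prediction of impacts for future exposures, and
    a synthetic panel generator for validation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    methods,
    stats,
    utils,
    S4Vectors,
    SummarizedExperiment,
    rjags,
    geosphere,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    MASS,
    withr,
    yaml,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
Collate:
    'AllGenerics.R'
    'AllClasses.R'
    'panel.R'
    'mcmodel.R'
    'estimands.R'
    'predictive.R'
    'simulate.R'
    'io.R'
    'pipeline.R'
    'tcExcess-package.R'
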