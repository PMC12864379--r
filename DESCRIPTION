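Package: esbafit
Title: Proportional-Odds Modelling of Repeated Frankl-Scale Ratings with
    Bootstrap-BIC Model Selection
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for analysing repeated ordinal behaviour ratings (the
    four-level Frankl scale) collected across the phases of a sensory-based
    dental-care programme (ESBA) for autistic children. Provides a
    maximum-likelihood fitter for cumulative logit models with and without
    proportional odds, exhaustive enumeration of candidate models with a
    single phase-by-covariate interaction, bootstrap-BIC model selection with
    the one-standard-error rule, cohort-specific improvement probabilities
    with percentile bootstrap confidence intervals, the Stuart-Maxwell test
    of marginal homogeneity, and a synthetic cohort generator with known
    ground truth for validation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports: stats, utils, graphics
Suggests: testthat (>= 3.0.0), MASS, withr, jsonlite
Config/testthat/edition: 3
RoxygenNote: 7.3.3
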