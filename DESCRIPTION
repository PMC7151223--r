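Package: urnings
Title: Urn-Based Rating System for Tracking Abilities and Difficulties
Version: 1.0.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Tracks person abilities and item difficulties in adaptive
    learning and testing systems with the Urnings rating system: every
    person and item is represented by a finite urn of green and red
    marbles whose green proportion estimates the inverse-logit of a
    Rasch-model trait. Updates are Metropolis-Hastings moves whose
    invariant distribution is exactly binomial, so standard errors and
    confidence intervals are known by design; an extra acceptance factor
    corrects for adaptive item selection so that matchmaking does not
    inflate the rating variance. Includes an Elo Rating System baseline,
    a Rasch-governed population and session simulator with adaptive
    matchmaking, core-subset scale anchoring, response-log replay, and an
    evaluation suite (correlation with true traits, binomial-interval
    coverage, rating-spread trajectories, calibration, and
    distributional diagnostics).
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    graphics,
    jsonlite
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
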