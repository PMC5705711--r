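Package: occudesign
Title: Occupancy Model Fitting, Survey Design Evaluation and Power Analysis
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for designing and evaluating detection/non-detection
    monitoring programmes for rare species. Fits single-season site-occupancy
    models with imperfect detection and covariates on logit links, ranks
    candidate models by AIC with Akaike weights through a two-stage stepwise
    selection, computes the minimum number of repeat visits needed to infer
    absence from an unoccupied site, evaluates estimator precision of the
    occupancy and detection maximum-likelihood estimates under candidate
    (sites x occasions) survey designs by Monte-Carlo simulation, and computes
    analytic (Wald, probabilistic scale) and empirical statistical power to
    detect a change in occupancy between two survey periods, including the
    number of sites required for a target power. A synthetic-data generator
    produces study-shaped datasets (altitudinal zones, observer-dependent
    detection, ragged monthly visit schedules) with a known-truth ledger for
    end-to-end testing.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
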