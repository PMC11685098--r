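Package: roament
Title: Roaming Entropy and Curiosity-Driven Exploration Analysis
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Analysis workflow for virtual-reality free-exploration studies:
    computes path and head-direction roaming entropy from 60 Hz trajectory
    logs on occupancy grids, scores sketch maps (composites, inter-rater
    reliability, Cronbach's alpha with bootstrap intervals), and fits
    Bayesian multilevel models with within-person centring (a bivariate
    exploration model with correlated residuals, a trait-moderation model,
    a cognitive-map model and a within-person mediation analysis),
    summarised by posterior means and highest posterior density intervals.
    Includes a synthetic-cohort generator with a known ground-truth record
    so every stage is testable without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    coda,
    dplyr,
    readr,
    rjags,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    yaml
Suggests:
    jsonlite,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
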