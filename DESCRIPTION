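Package: mtordyn
Title: Single-Cell Analysis of mTORC1 Reporter Dynamics
Version: 0.1.0
Authors@R:
    person("Package", "Maintainer", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Tools for quantifying mTORC1 signaling dynamics in single cells
    from translocation-reporter and FRET-reporter time series and from
    multiplexed immunofluorescence tables. Provides seeded synthetic-data
    generators with known ground truth (latent-activity-driven reporter
    trajectories, condition-dependent stain tables, and two-channel reporter
    images), nuclear/cytoplasmic-ring segmentation and intensity measurement,
    trace quality filtering and gap interpolation, per-cell response metrics
    (initial and steady-state localization changes, FRET linearization,
    relative translation activity), volatility and lagged cross-correlation
    analysis with a scrambled-pair null, analog/digital dose-response
    classification, and partial least-squares regression variance
    decomposition of protein-synthesis labeling across phosphorylation
    panels.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    jsonlite,
    Rcpp,
    stats,
    utils
LinkingTo:
    Rcpp
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
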