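Package: occufuse
Title: Integrated Occupancy Species Distribution Models from Heterogeneous Survey Data
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Fits integrated species distribution models that combine
    structured single-visit surveys, multi-interval point counts, and
    semi-structured checklists through a shared latent occupancy process with
    protocol-specific observation models. Provides effort-dependent and
    false-positive detection models, checklist quality filtering and hexagonal
    spatial balancing, covariate-based integration of less reliable data,
    penalized-spline (GAM) occupancy surfaces sampled by adaptive MCMC, and a
    cross-validated Brier/AUC model-comparison experiment. Includes a full
    synthetic-data generator emulating the statistical structure of the three
    survey protocols so every stage is testable without field data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    mgcv,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    pROC
Config/testthat/edition: 3
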