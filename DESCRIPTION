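Package: tumorkinetics
Title: Tumor Growth Kinetics from Detection-Week and Histology Count Data
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Estimates mammary tumor growth rates from palpation
    detection-week and necropsy-mass records, deconvolves growth into
    cell-cycle duration (Ki67 proliferative fraction over mitotic index)
    and apoptotic duration via a proliferation/death mass-balance model,
    fits Poisson and negative-binomial models to overdispersed per-field
    mitotic and apoptotic counts, plans Ki67 image-field sampling by tumor
    size with hotspot allocation, normalizes protein-expression panels to
    a loading control, and evaluates multivariate structure with NIPALS
    principal components (R2X, cross-validated Q2), a two-group Hotelling
    T-squared test, and single-component PLS regression of tumor mass on
    the predictor panel. Includes a synthetic-cohort generator so the
    whole pipeline is testable without animal data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    tools,
    MASS,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
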