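Package: dsmorph
Title: Dense Surface Models for 3D Facial Morphometry
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Builds dense surface models (DSMs) of 3D facial surfaces for
    syndrome dysmorphology analysis. From sparse anatomical landmarks a dense
    point correspondence is induced across a cohort (generalized Procrustes
    alignment, thin-plate-spline warping of a base mesh, closest-point surface
    projection); principal-component shape modes are extracted from the
    corresponded points; individual faces are characterized by normalized
    signatures against age- and sex-matched control statistics, scalar
    dysmorphism scores and red-green-blue heat maps; groups are compared by
    landmark anthropometry with Bonferroni-corrected Student's t-tests,
    multi-fold discrimination in mode-score space, and regression of growth
    markers against age. A deterministic synthetic face-cohort generator with
    controlled group effects, growth, individual variation and sensor noise
    provides a fully reproducible test bed.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    MASS,
    e1071,
    jsonlite,
    yaml,
    stats,
    utils,
    graphics,
    grDevices
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    vegan,
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
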