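Package: spinestiff
Title: Specimen-Specific Intervertebral Joint Stiffness Identification
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Quasi-static multibody modelling of the thoracolumbar spine
    (T12-sacrum) with six-degree-of-freedom bushing joints, simulation of
    pure-moment flexibility tests, and identification of specimen-specific
    rotational intervertebral joint stiffnesses by bounded minimisation of
    the kinematic tracking error. Supports uniform and fixed-ratio
    level-dependent stiffness representations, leave-one-out
    cross-validation across a specimen cohort, kinematic error metrics
    (MAE, RMSE, percentage errors), and the associated nonparametric
    statistics (Kruskal-Wallis with permutation critical values, Wilcoxon
    signed-rank with Bonferroni correction). Includes a synthetic-cohort
    generator with known ground-truth stiffnesses so the full pipeline is
    testable end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    graphics,
    jsonlite
Suggests:
    withr,
    testthat (>= 3.0.0),
    yaml,
Config/testthat/edition: 3
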