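Package: tyroqsar
Title: QSAR Modelling of MMP-2 Inhibitors with 3D Descriptors, CDFS-MLR and GA-PLS
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for building and validating quantitative structure-activity
    relationship (QSAR) models of matrix metalloproteinase-2 (MMP-2)
    inhibitors built on an L-tyrosine scaffold. Computes named 3D and
    topological molecular descriptors (3D-MoRSE, radial distribution
    function, WHIM, GETAWAY, Geary autocorrelation, information content,
    shape profiles, quantum indices) from SDF/XYZ structures; cleans and
    splits descriptor matrices; fits multiple linear regression models by
    stepwise selection with a combined data splitting-feature selection
    (CDFS) strategy and by genetic-algorithm partial least squares (GA-PLS);
    validates models by leave-one-out cross-validation, Y-randomization and
    a leverage-based applicability domain (Williams plot); and ships the
    published final equations and reference activity table as ready-to-use
    predictors.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    graphics,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
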