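Package: replifit
Title: Replicator-Dynamics Model Fitting for Two-Phenotype Tumor Frequency Data
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for analysing frequency time series of two competing tumor
    cell phenotypes (adrenergic/ADRN and mesenchymal/MES neuroblastoma cells)
    with evolutionary game theory. Implements four replicator-dynamics models
    (baseline competition, baseline with background phenotype transitions,
    therapy-induced cell-type death, and therapy-induced cell-state switching),
    piecewise on/off treatment schedules, bounded Levenberg-Marquardt
    least-squares calibration, R-squared and AIC model discrimination, a
    fixed-switching-rate profile sweep, and a seeded synthetic-data generator
    that emulates flow-cytometry frequency measurements under control and
    repeated-chemotherapy experimental designs.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    deSolve,
    minpack.lm,
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
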