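Package: stabval
Title: Stability-Indicating HPLC Method Validation and Degradation Kinetics
Version: 0.1.0
Authors@R:
    person("Esmeralda", "Reyes", email = "stabval@example.org", role = c("aut", "cre"))
Description: Tools for the computational side of a stability-indicating HPLC
    assay study: ICH Q2 method-validation statistics (system and method
    linearity, accuracy and precision, detection and quantification limits
    from calibration regression, robustness, specificity), chromatographic
    figures of merit (capacity factor, resolution, peak integration),
    first-order forced-degradation kinetics with Arrhenius adjustment across
    temperatures and t90 shelf-life estimation, a fully seeded synthetic-data
    generator with known ground truth, and a command-line interface producing
    validation and stability reports.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
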