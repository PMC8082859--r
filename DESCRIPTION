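Package: cpdrift
Title: Conformal Prediction Diagnostics for Data Drift in Toxicity Modelling
Version: 0.1.0
Authors@R: person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Mondrian inductive conformal prediction for binary toxicity
    classification, with aggregated (ACP) and synergy (SCP) variants,
    calibration-and-efficiency diagnostics, and model update strategies for
    restoring calibration when chronologically released datasets drift.
    Includes a signature molecular descriptor (atom-rooted canonical
    fragments, heights 1-3), a molecule standardisation pipeline built on
    ChemmineR/OpenBabel, and a synthetic drifted-batch generator so the whole
    workflow is testable without external downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    ChemmineR,
    ChemmineOB,
    Matrix,
    e1071,
    ggplot2,
    jsonlite,
    yaml,
    stats,
    utils,
    methods
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
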