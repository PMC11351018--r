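Package: forceuq
Title: Calibrated and Spatially Resolved Uncertainty for Committee Force
    Predictions
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Tools for turning the spread of an ensemble (committee) of
    machine-learning interatomic potentials into calibrated, spatially
    resolved force-error estimates.  Computes per-component committee means
    and unbiased standard deviations, aggregates them into per-atom,
    local (neighbor-shell, within a cutoff radius) and per-structure
    scalars under periodic boundary conditions, fits the
    error/uncertainty proportionality constant alpha and predicts
    absolute force errors from it, evaluates calibration through
    sparsification and oracle curves, validates the underlying
    statistics with a variance-only Monte Carlo committee simulator, and
    drives an active-learning geometry pipeline that selects
    high-uncertainty frames from a trajectory, cuts density-preserving
    subboxes around the most uncertain atom and relaxes their borders in
    stages.  Reads and writes multi-frame extended-XYZ with per-member
    force columns.
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
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
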