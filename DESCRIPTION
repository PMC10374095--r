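Package: slowwave
Title: Simulation, Preprocessing and Classification of Gastric Myoelectric Recordings
Version: 0.1.0
Authors@R: person("Pkg", "Maintainer", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Tools for studying gastric slow-wave (electrogastrographic) activity
    recorded from serosal electrodes in freely moving animals.  Provides a seeded
    synthetic multichannel recording generator with amplifier-saturation and
    movement artifacts, a five-stage preprocessing chain (anti-aliased decimation,
    saturation zeroing, zero-phase Butterworth band-pass filtering, artifact
    interpolation and channel quality control), Welch band-power featurization
    with sequential feature selection, five shallow classifiers with calibrated
    probability outputs, a 1-D residual convolutional network trained with
    early stopping, and ROC/AUC evaluation under repeated stratified k-fold
    cross-validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    data.table,
    MASS,
    quadprog,
    stats,
    utils,
    yaml,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
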