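Package: engdecode
Title: Decoding Bladder State from Multichannel Pudendal Nerve Recordings
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Offline decoding of bladder filling state (baseline, full,
    micturition) from multichannel peripheral-nerve electroneurogram (ENG)
    recordings acquired with intrafascicular multichannel electrodes. The
    package provides a synthetic multi-channel ENG session generator
    (Poisson-with-dead-time spike trains, biphasic extracellular waveforms,
    dead channels, broadband noise, physiological pressure/volume traces),
    zero-phase Butterworth band-pass preprocessing with undersampling and
    MAD-threshold spike-detection quality control, sliding-window extraction
    of nine myoelectric-style features per channel, leakage-safe train/test
    splitting and standardization, nested cross-validation with grid search
    over random forest, support vector machine, k-nearest-neighbour and
    multi-layer perceptron classifiers scored by balanced accuracy, Gini
    feature importance aggregated per feature and per recording site, and a
    window-length sweep with a trade-off selection rule.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    graphics,
    signal,
    ranger,
    e1071,
    class,
    jsonlite
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
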