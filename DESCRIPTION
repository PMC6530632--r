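Package: phasekin
Title: Low-Delta EEG Phase Decoding of Center-Out Hand Movements
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.com", role = c("aut", "cre"))
Description: Reconstructs two-dimensional center-out hand movement kinematics
    (position and velocity) from multichannel EEG using the instantaneous
    phase of the low-delta (0.1-1 Hz) band. Implements the full decoding
    pipeline: common-average referencing, zero-phase Butterworth band
    filtering via second-order sections, Hilbert-transform phase, amplitude
    and sliding-window bandpower features, time-lag embedding, multiple
    linear regression and Kalman-filter decoders with least-squares system
    identification, channel-level movement-contrast statistics (effect size,
    feature-speed correlation, activation index), block-wise six-fold
    cross-validation with shuffle-based chance levels, and a seeded synthetic
    center-out session generator for testing and benchmarking.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    signal,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr,
    jsonlite,
    optparse,
    yaml
Config/testthat/edition: 3
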