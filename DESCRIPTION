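Package: hystereon
Title: Estimation and Forecasting of Respiratory Tissue Hysteresivity from
    Forced-Oscillation and Wearable-Sensor Data
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.com",
    role = c("aut", "cre"))
Description: Tools for respiratory mechanics monitoring that combine forced
    oscillation technique (FOT) lung function measurements with continuous
    wearable-sensor streams. Implements constant-phase impedance model
    identification yielding tissue damping, elastance and hysteresivity
    (eta); a two-hour alternating FOT/RESMON measurement protocol with
    multi-rate stream synchronization; recurrent (LSTM) sequence models that
    estimate per-session eta from continuous heart rate using sparse
    calibration measurements, and that forecast eta one measurement interval
    ahead via a dual-step ECG-to-heart-rate-to-eta scheme; a seeded
    synthetic-data generator providing ground-truth sessions for validation;
    and the evaluation metrics (MSE, R2, NRMSE fit, paired tests) used to
    score estimation and forecasting performance.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite,
    minpack.lm,
    pracma
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
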