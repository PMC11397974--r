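# hystereon

Estimation and forecasting of respiratory **tissue hysteresivity (η)** from
forced-oscillation lung function tests combined with continuous
wearable-sensor streams.

## What it does, and for whom

Forced oscillation technique (FOT) testing yields the complex respiratory
impedance `Z(jω)`. Fitting the constant-phase tissue model

    Z(jω) = R + jωL + (G − jH)·ω^(−α),   G = D·cos(απ/2),  H = D·sin(απ/2)

gives tissue damping `G` and elastance `H`, whose ratio

    η = G / H = cot(απ/2)

indexes lung tissue heterogeneity and remodelling. Tracking η through a
session normally requires repeated device measurements. This package — aimed
at respiratory-mechanics and physiological-monitoring researchers —
implements a measurement-reduction pipeline:

1. **Protocol**: a two-hour schedule alternating a low-frequency FOT
   prototype (0.2–2 Hz, 2-min measurements) and a RESMON-class device
   (5–37 Hz, 1-min measurements) across 10 sessions (125 min total), with
   2-min wearable-extraction windows co-timed with the FOT measurements.
2. **Impedance identification**: spectra from multisine pressure/flow
   records, constant-phase fits by multistart nonlinear least squares, η per
   session and band.
3. **Estimation**: an LSTM (1 × 50 hidden units) trained per subject on
   *three* calibration sessions (1, 5, 10) maps 1-min windows of 1-Hz heart
   rate to η for the remaining seven sessions — a ten-to-three reduction in
   device measurements.
4. **Forecasting**: a dual-step scheme — beat detection on two-lead ECG
   gives 1-Hz HR per session window; a 2 × 150-unit LSTM forecasts the next
   window's HR one inter-measurement interval ahead (11 min FOT / 12 min
   RESMON); forecast HR feeds the estimator to forecast η. A 2 × 100-unit
   sequence-to-sequence LSTM additionally reconstructs ECG Lead II from
   Lead I.
5. **Synthetic cohorts**: a seeded generator producing complete subject
   sessions (HR, two-lead ECG, slow channels, per-session constant-phase
   parameters with an HR-coupled η, multisine FOT records) so the whole
   pipeline is testable with known ground truth.

The recurrent engine (LSTM forward/backward, full-batch Adam) is implemented
in the package in vectorized R over BLAS and is verified against numerical
gradients in the test suite.

## Worked example

```r
library(hystereon)

tl <- build_timeline()
tl$total_duration                      # 125 (minutes)
inter_measurement_interval(tl, "FOT")  # 11

# one synthetic subject with known ground truth
prof <- sample_subject_profiles(1, seed = 7)[[1]]
ses  <- synthetic_session(prof, tl)

# identify eta from the session-1 low-band FOT record
rec <- ses$fot$low[[1]]
sp  <- estimate_spectrum(rec$pressure, rec$flow, rec$grid, rec$fs, band = "low")
fit <- fit_constant_phase(sp)
fit
#> <constant_phase_params> R = 2.785, L = 0.0004563, D = 5.647, alpha = 0.4395 |
#>   G = 4.354, H = 3.596, eta = 1.211

# estimate eta for all 10 sessions from HR, calibrating on sessions 1, 5, 10
segs  <- align_stream(preprocess_stream(ses$streams$hr), eqv_extraction_windows(tl))
calib <- calibration_set(c(1, 5, 10), ses$true_eta[c(1, 5, 10)])
prep  <- prepare_sequences(segs, calib, sequence_model_config(seed = 11))
est   <- train_estimator(prep)
head(estimate_eta(est, prep), 4)
#>   session_index  eta_hat      source
#> 1             1 1.296973 calibration
#> 2             2 1.275534       model
#> 3             3 1.428436       model
#> 4             4 1.428486       model
```

`eta_hat` for `source = "model"` sessions comes from the trained network;
calibration sessions echo their measured value. Against this subject's
generator truth the seven model-sourced estimates have a mean absolute error
of ≈ 0.09 — the irreducible session-to-session η noise under the default
coupling. The full per-subject pipeline (both bands, estimation + dual-step
forecast, artifacts and manifest on disk) is one call:

```r
run_pipeline(run_config(n_subjects = 1, seed = 1), out_dir = "run_out")
```

A thin command-line front end with per-stage subcommands (`simulate`,
`schedule`, `fit-impedance`, `predict-lead`, `run`) is installed at
`inst/cli/hystereon.R`.

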