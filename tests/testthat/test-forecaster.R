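test_that("ECG-derived HR matches the generating profile", {
  ses <- demo_session()
  tl <- ses$timeline
  leads <- list(lead1 = ses$streams$ecg_lead1, lead2 = ses$streams$ecg_lead2)
  hr_ecg <- derive_hr_input(leads, tl)
  expect_length(hr_ecg, 10L)
  # against the generator's windowed HR: mean absolute error below 2 bpm
  segs <- align_stream(ses$streams$hr, eqv_extraction_windows(tl))
  maes <- vapply(
    1:10,
    function(k) mean(abs(hr_ecg[[k]]$value - segs[[k]]$value)), numeric(1)
  )
  expect_lt(mean(maes), 2)
  expect_error(
    derive_hr_input(list(lead1 = leads$lead1), tl),
    "invalid-argument"
  )
})

test_that("constant-HR ECG yields a constant derived HR near 60", {
  p <- subject_profile("S1", 30, 70, 175, 60, 1.2, seed = 3)
  tl <- build_timeline(n_sessions = 1)
  hr <- generate_hr_profile(tl$total_duration * 60, p, drift_sd = 0, noise_sd = 0)
  ecg <- generate_ecg(hr, seed = 2, fs = 128, noise_sd = 0)
  out <- derive_hr_input(list(lead1 = ecg$lead1, lead2 = ecg$lead2), tl)
  expect_lt(max(abs(out[[1]]$value - 60)), 1)
})

test_that("HR forecasting handles constants, trends and reseeding", {
  cfg <- forecast_config(hidden_units = 20L, max_epochs = 100L, seed = 4)
  # constant across sessions: forecast equals the constant
  const_sessions <- lapply(1:6, function(k) rep(72, 60))
  fc <- train_hr_forecaster(const_sessions, cfg)
  pred <- forecast_hr(fc, const_sessions)
  expect_equal(pred[["6"]], rep(72, 60), tolerance = 1e-2)
  # deterministic linear trend: the forecast continues it
  trend_sessions <- lapply(1:8, function(k) rep(60 + 2 * k, 60))
  fc2 <- train_hr_forecaster(trend_sessions, forecast_config(
    hidden_units = 30L, max_epochs = 200L, loss_tol = 1e-8, seed = 4
  ))
  pred2 <- forecast_hr(fc2, trend_sessions)
  expect_equal(pred2[["8"]], rep(76, 60), tolerance = 0.05 * 76)
  # same seed twice: identical forecasts
  fc3 <- train_hr_forecaster(trend_sessions, forecast_config(
    hidden_units = 30L, max_epochs = 200L, loss_tol = 1e-8, seed = 4
  ))
  expect_identical(forecast_hr(fc3, trend_sessions), pred2)
  expect_error(train_hr_forecaster(const_sessions[1:2], cfg), "at least 3")
})

test_that("an error-free HR forecast reproduces the estimation path exactly", {
  set.seed(41)
  segs <- lapply(1:10, function(k) {
    s <- sensor_stream((k - 1) * 780 + 0:119, rnorm(120, 65 + k, 2), fs = 1)
    attr(s, "session_index") <- k
    s
  })
  calib <- calibration_set(c(1L, 5L, 10L), c(1.1, 1.3, 1.5))
  cfg <- sequence_model_config(hidden_units = 10L, max_epochs = 40L, seed = 9)
  prep <- prepare_sequences(segs, calib, cfg)
  est <- train_estimator(prep)
  est_path <- estimate_eta(est, prep)
  # inject the true HR windows as the "forecast"
  oracle_fc <- lapply(2:10, function(k) segs[[k]]$value)
  names(oracle_fc) <- as.character(2:10)
  fc_path <- forecast_eta(oracle_fc, est, calib)
  for (k in 2:10) {
    expect_identical(
      fc_path$eta_hat[fc_path$session_index == k],
      est_path$eta_hat[est_path$session_index == k]
    )
  }
  expect_true(all(fc_path$source[!fc_path$session_index %in% c(5, 10)] == "forecast"))
  expect_error(forecast_eta(oracle_fc, "not a model", calib), "invalid-argument")
})

test_that("forecast horizons equal the device inter-measurement intervals", {
  tl <- default_timeline()
  expect_equal(forecast_config(horizon_min = 11)$horizon_min,
    inter_measurement_interval(tl, "FOT"))
  expect_equal(forecast_config(horizon_min = 12)$horizon_min,
    inter_measurement_interval(tl, "RESMON"))
})

test_that("lead reconstruction learns identity and affine maps almost perfectly", {
  expect_gte(lead_fit_identity()$report$fit_percent, 99)
  expect_gte(lead_fit_affine()$report$fit_percent, 95)
})

test_that("lead reconstruction handles the morphing transform and bad input", {
  fit <- lead_fit_morph()
  expect_gt(fit$report$fit_percent, 60)
  s <- lead_fixture_streams()
  short <- sensor_stream(0:99 / 128, s$clean$lead1$value[1:100], fs = 128)
  expect_error(predict_lead2_from_lead1(s$clean$lead1, short), "differ in length")
})
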