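seg_stream <- function(values, session, t0 = 0) {
  s <- sensor_stream(t0 + seq_along(values) - 1, values, fs = 1, channel = "hr")
  attr(s, "session_index") <- session
  s
}

test_that("window preparation counts and pools follow the stride-1 rule", {
  segs <- lapply(1:10, function(k) seg_stream(rnorm(120, 70, 2), k, (k - 1) * 780))
  calib <- calibration_set(c(1L, 5L, 10L), c(1.1, 1.2, 1.3))
  prep <- prepare_sequences(segs, calib, sequence_model_config(input_window = 60L))
  # count oracle: len - window + 1 = 61 windows per session
  expect_equal(dim(prep$infer[["2"]])[1], 61L)
  # training pool from exactly the 3 calibration sessions
  expect_equal(dim(prep$train$X)[1], 3L * 61L)
  expect_setequal(prep$train$sessions, c(1L, 5L, 10L))
  # full-length window: exactly one per session
  prep1 <- prepare_sequences(segs, calib, sequence_model_config(input_window = 120L))
  expect_equal(dim(prep1$infer[["3"]])[1], 1L)
  # labels echo the calibration values (normalized round trip)
  labs <- unique(prep$train$y * prep$y_norm["sd"] + prep$y_norm["mean"])
  expect_equal(sort(unname(labs)), c(1.1, 1.2, 1.3), tolerance = 1e-12)
})

test_that("short segments and missing calibration sessions are rejected", {
  segs <- lapply(1:10, function(k) seg_stream(rnorm(30, 70, 2), k))
  calib <- calibration_set(c(1L, 5L, 10L), c(1, 1, 1))
  expect_error(
    prepare_sequences(segs, calib, sequence_model_config(input_window = 60L)),
    "session 1.*shorter"
  )
  segs120 <- lapply(1:4, function(k) seg_stream(rnorm(120, 70, 2), k))
  expect_error(
    prepare_sequences(segs120, calib, sequence_model_config()),
    "calibration sessions missing"
  )
})

test_that("a constant-eta record is fitted to the constant", {
  set.seed(31)
  segs <- lapply(1:4, function(k) seg_stream(rnorm(40, 70, 2), k))
  calib <- calibration_set(c(1L, 2L, 4L), rep(1.25, 3))
  cfg <- sequence_model_config(
    hidden_units = 8L, input_window = 20L,
    max_epochs = 300L, loss_tol = 1e-8, seed = 5
  )
  prep <- prepare_sequences(segs, calib, cfg)
  est <- train_estimator(prep)
  out <- estimate_eta(est, prep)
  expect_equal(out$eta_hat, rep(1.25, 4), tolerance = 1e-3)
})

test_that("two well-separated HR levels map to their eta values", {
  set.seed(32)
  lvl <- c(60, 60, 90, 90, 60, 90) # sessions alternate between two states
  eta <- c(0.9, 0.9, 1.8, 1.8, 0.9, 1.8)
  segs <- lapply(1:6, function(k) seg_stream(rnorm(60, lvl[k], 1), k))
  calib <- calibration_set(c(1L, 3L, 5L), eta[c(1, 3, 5)])
  cfg <- sequence_model_config(
    hidden_units = 16L, input_window = 30L, max_epochs = 150L, seed = 6
  )
  prep <- prepare_sequences(segs, calib, cfg)
  est <- train_estimator(prep)
  out <- estimate_eta(est, prep)
  held <- out[out$source == "model", ]
  expect_equal(held$eta_hat, eta[held$session_index], tolerance = 0.05 * 1.8)
})

test_that("training and estimation are deterministic under a fixed seed", {
  set.seed(33)
  segs <- lapply(1:5, function(k) seg_stream(rnorm(40, 70, 3), k))
  calib <- calibration_set(c(1L, 3L, 5L), c(1.0, 1.2, 1.4))
  cfg <- sequence_model_config(
    hidden_units = 8L, input_window = 20L, max_epochs = 50L, seed = 17
  )
  prep <- prepare_sequences(segs, calib, cfg)
  a <- estimate_eta(train_estimator(prep), prep)
  b <- estimate_eta(train_estimator(prep), prep)
  expect_identical(a, b)
})

test_that("calibration sessions pass through and counts obey the 10-to-3 reduction", {
  set.seed(34)
  segs <- lapply(1:10, function(k) seg_stream(rnorm(120, 70, 2), k))
  # all sessions calibrated: output echoes the measurements everywhere
  etas <- seq(1, 1.9, by = 0.1)
  calib_all <- calibration_set(1:10, etas)
  cfg <- sequence_model_config(hidden_units = 4L, max_epochs = 5L, seed = 2)
  prep_all <- prepare_sequences(segs, calib_all, cfg)
  out_all <- estimate_eta(train_estimator(prep_all), prep_all)
  expect_equal(out_all$eta_hat, etas)
  expect_true(all(out_all$source == "calibration"))
  # default calibration: estimates exist for all 10 sessions, 3 measured + 7 modelled
  calib <- calibration_set(c(1L, 5L, 10L), etas[c(1, 5, 10)])
  prep <- prepare_sequences(segs, calib, cfg)
  out <- estimate_eta(train_estimator(prep), prep)
  expect_equal(nrow(out), 10L)
  expect_equal(sum(out$source == "model"), 7L)
  expect_equal(sum(out$source == "calibration"), 3L)
})

test_that("noise-free linear HR-eta coupling is recovered per held-out session", {
  tl <- default_timeline()
  win <- eqv_extraction_windows(tl)
  p <- subject_profile("S1", 30, 70, 175, 72, 1.3,
    coupling_gamma = 1, noise_sd_eta = 0, seed = 12
  )
  hr <- generate_hr_profile(tl$total_duration * 60, p)
  segs <- align_stream(hr, win)
  m <- vapply(segs, function(x) mean(x$value), numeric(1))
  true_eta <- vapply(generate_session_params(p, m), `[[`, numeric(1), "eta")
  calib <- calibration_set(c(1L, 5L, 10L), true_eta[c(1, 5, 10)])
  cfg <- sequence_model_config(hidden_units = 25L, seed = 13)
  prep <- prepare_sequences(segs, calib, cfg)
  out <- estimate_eta(train_estimator(prep), prep)
  held <- out[out$source == "model", ]
  rel <- abs(held$eta_hat - true_eta[held$session_index]) / true_eta[held$session_index]
  expect_lt(max(rel), 0.05)
})

test_that("calibration sets validate their invariants", {
  expect_error(calibration_set(c(1, 5), c(1, 2, 3)), "one measured eta")
  expect_error(calibration_set(c(1, 1, 5), c(1, 2, 3)), "duplicated")
  expect_error(calibration_set(c(0, 5, 10), c(1, 2, 3)), "1-based")
})
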