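#' Forecaster configuration
#'
#' Defaults follow the dual-step forecasting architecture: two LSTM layers
#' of 150 hidden units predicting the next measurement window's heart-rate
#' sequence, one inter-measurement interval ahead (11 min for the FOT
#' device, 12 min for RESMON).
#'
#' @param hidden_units LSTM width (default 150).
#' @param n_layers Stacked LSTM layers (default 2).
#' @param horizon_min Prediction horizon in minutes (11 or 12 by default,
#'   per device).
#' @param max_epochs Maximum training epochs (default 200).
#' @param learning_rate Adam step size (default 0.01).
#' @param split_ratio Chronological fraction of session transitions used for
#'   training (default 0.7).
#' @param loss_tol Convergence floor on the training MSE of the normalized
#'   targets (default 5e-4); see [lstm_train()].
#' @param seed Integer seed.
#' @return A list of class `forecast_config`.
#' @export
forecast_config <- function(hidden_units = 150L, n_layers = 2L,
                            horizon_min = 11, max_epochs = 200L,
                            learning_rate = 0.01, split_ratio = 0.7,
                            loss_tol = 5e-4, seed = 1L) {
  if (n_layers < 1) stop("invalid-argument: 'n_layers' must be >= 1")
  structure(
    list(
      hidden_units = as.integer(hidden_units), n_layers = as.integer(n_layers),
      horizon_min = horizon_min, max_epochs = as.integer(max_epochs),
      learning_rate = learning_rate, split_ratio = split_ratio,
      loss_tol = loss_tol, seed = as.integer(seed)
    ),
    class = "forecast_config"
  )
}

#' Lead I to Lead II predictor configuration
#'
#' Defaults follow the lead-reconstruction architecture: two LSTM layers of
#' 100 hidden units outputting sequences, a fully connected layer to output
#' size 1, Adam with at most 200 epochs, and a 70:30 chronological
#' train/validation split.
#'
#' @param hidden_units LSTM width (default 100).
#' @param n_layers Stacked LSTM layers (default 2).
#' @param max_epochs Maximum training epochs (default 200).
#' @param learning_rate Adam step size (default 0.01).
#' @param split_ratio Chronological train fraction (default 0.7).
#' @param window,stride Sub-sequence length and hop (in samples) used to
#'   batch the training signal.
#' @param loss_tol Convergence floor on the training MSE of the normalized
#'   signal (default 1e-5); see [lstm_train()].
#' @param seed Integer seed.
#' @return A list of class `lead_predict_config`.
#' @export
lead_predict_config <- function(hidden_units = 100L, n_layers = 2L,
                                max_epochs = 200L, learning_rate = 0.01,
                                split_ratio = 0.7, window = 128L,
                                stride = 64L, loss_tol = 1e-5, seed = 1L) {
  structure(
    list(
      hidden_units = as.integer(hidden_units), n_layers = as.integer(n_layers),
      max_epochs = as.integer(max_epochs), learning_rate = learning_rate,
      split_ratio = split_ratio, window = as.integer(window),
      stride = as.integer(stride), loss_tol = loss_tol,
      seed = as.integer(seed)
    ),
    class = "lead_predict_config"
  )
}

# R-peak detection: local maxima above half the upper amplitude range with a
# refractory distance corresponding to 180 beats/min.
detect_beats <- function(values, fs) {
  thr <- min(values) + 0.6 * (max(values) - min(values))
  pk <- pracma::findpeaks(values,
    minpeakheight = thr,
    minpeakdistance = max(1L, floor(fs * 60 / 180))
  )
  if (is.null(pk)) return(numeric(0))
  sort(pk[, 2L])
}

#' Derive per-session heart-rate input from the ECG leads
#'
#' For each wearable extraction window of the protocol, detects R peaks on
#' ECG Lead II (falling back to Lead I if detection quality is poor),
#' converts beat-to-beat intervals to instantaneous heart rate, resamples it
#' at 1 Hz over the window, and applies the standard HR cleaning pipeline.
#' A window where beats are undetectable over more than 10\% of its duration
#' raises a quality error naming the session.
#'
#' @param ecg_leads List with [sensor_stream()]s `lead1` and `lead2`.
#' @param timeline A [build_timeline()] result covering the leads.
#' @param cfg A [preprocess_config()] for the HR cleaning step.
#' @return A list of per-session 1-Hz HR [sensor_stream()] segments with
#'   `session_index` attributes (same shape as [align_stream()] output).
#' @export
derive_hr_input <- function(ecg_leads, timeline, cfg = preprocess_config()) {
  for (nm in c("lead1", "lead2")) {
    if (is.null(ecg_leads[[nm]]) || nrow(ecg_leads[[nm]]) == 0L) {
      stop("invalid-argument: empty or missing ECG lead '", nm, "'")
    }
  }
  windows <- eqv_extraction_windows(timeline)
  seg2 <- align_stream(ecg_leads$lead2, windows)
  seg1 <- align_stream(ecg_leads$lead1, windows)
  lapply(seq_len(nrow(windows)), function(i) {
    fs <- attr(seg2[[i]], "fs")
    dur <- (windows$end[i] - windows$start[i]) * 60
    beats_from <- function(seg) seg$t_s[detect_beats(seg$value, fs)]
    bt <- beats_from(seg2[[i]])
    gap_bad <- function(b) {
      if (length(b) < 3L) return(dur)
      gaps <- diff(c(windows$start[i] * 60, b, windows$end[i] * 60))
      sum(gaps[gaps > 2]) # stretches with no beat for > 2 s (HR < 30)
    }
    if (gap_bad(bt) > 0.1 * dur) bt <- beats_from(seg1[[i]]) # fallback: Lead I
    if (gap_bad(bt) > 0.1 * dur) {
      stop(sprintf(
        "quality error: undetectable beats over > 10%% of session %d window",
        windows$session_index[i]
      ))
    }
    rr <- diff(bt)
    hr_inst <- 60 / rr
    t_mid <- (bt[-1L] + bt[-length(bt)]) / 2
    t_grid <- seq(windows$start[i] * 60, windows$end[i] * 60 - 1, by = 1)
    hr_1hz <- stats::approx(t_mid, hr_inst, xout = t_grid, rule = 2L)$y
    seg <- sensor_stream(t_grid, hr_1hz, fs = 1, channel = "hr_ecg", units = "bpm")
    seg <- preprocess_stream(seg, cfg)
    attr(seg, "session_index") <- windows$session_index[i]
    seg
  })
}

#' Train the session-to-session heart-rate forecaster
#'
#' Builds transition pairs (session `k` window as input, session `k+1`
#' window as target, both 1-Hz sequences of equal length), trains the
#' two-layer LSTM on the chronologically first `split_ratio` fraction of
#' transitions, and normalizes inputs and targets with training-portion
#' statistics only.
#'
#' @param hr_sessions List of per-session HR segments ([sensor_stream()]s or
#'   numeric vectors of equal length, chronological order).
#' @param cfg A [forecast_config()].
#' @return A list of class `hr_forecaster`.
#' @export
train_hr_forecaster <- function(hr_sessions, cfg = forecast_config()) {
  vals <- lapply(hr_sessions, function(s) if (is_sensor_stream(s)) s$value else as.numeric(s))
  n <- length(vals)
  if (n < 3L) stop("invalid-argument: need at least 3 sessions of history")
  len <- unique(vapply(vals, length, integer(1)))
  if (length(len) != 1L) {
    stop("invalid-argument: session windows must have equal length")
  }
  n_pairs <- n - 1L
  n_train <- max(2L, min(n_pairs, ceiling(cfg$split_ratio * n_pairs)))
  train_in <- do.call(rbind, lapply(seq_len(n_train), function(k) vals[[k]]))
  train_out <- do.call(rbind, lapply(seq_len(n_train), function(k) vals[[k + 1L]]))
  m <- mean(train_in)
  s <- sqrt(mean((train_in - m)^2))
  if (s <= 0) s <- 1
  X <- array((train_in - m) / s, c(n_train, len, 1L))
  Y <- (train_out - m) / s
  model <- lstm_init(
    input_size = 1L, hidden_units = cfg$hidden_units, n_layers = cfg$n_layers,
    output_size = len, head = "last", seed = cfg$seed
  )
  model <- lstm_train(model, X, Y,
    learning_rate = cfg$learning_rate, max_epochs = cfg$max_epochs,
    loss_tol = cfg$loss_tol
  )
  structure(
    list(
      model = model, norm = c(mean = m, sd = s), len = len, cfg = cfg,
      n_train_pairs = n_train,
      loss_history = attr(model, "loss_history")
    ),
    class = "hr_forecaster"
  )
}

#' Forecast the next sessions' heart-rate windows
#'
#' Applies the trained forecaster to every observed session window `k`,
#' producing the forecast HR sequence for session `k+1` (one
#' inter-measurement interval ahead).
#'
#' @param forecaster A [train_hr_forecaster()] result.
#' @param hr_sessions The observed per-session HR segments.
#' @return A named list mapping forecast session index (`2 .. n`) to a 1-Hz
#'   HR vector in beats/min.
#' @export
forecast_hr <- function(forecaster, hr_sessions) {
  stopifnot(inherits(forecaster, "hr_forecaster"))
  vals <- lapply(hr_sessions, function(s) if (is_sensor_stream(s)) s$value else as.numeric(s))
  m <- forecaster$norm["mean"]; s <- forecaster$norm["sd"]
  out <- lapply(seq_len(length(vals) - 1L), function(k) {
    X <- array((vals[[k]] - m) / s, c(1L, forecaster$len, 1L))
    as.numeric(lstm_predict(forecaster$model, X)) * s + m
  })
  names(out) <- as.character(seq_len(length(vals) - 1L) + 1L)
  out
}

#' Forecast eta by composing the HR forecast with the trained estimator
#'
#' The dual-step scheme: forecast HR windows feed the estimation model
#' exactly as recorded HR would, so an error-free HR forecast reproduces the
#' estimation-path eta bit for bit. Calibration sessions pass through their
#' measured value; all other forecastable sessions are flagged
#' `source = "forecast"`.
#'
#' @param hr_forecast Named list of forecast HR vectors per session index,
#'   from [forecast_hr()].
#' @param estimator A trained [train_estimator()] result.
#' @param calibration A [calibration_set()].
#' @return A data frame with columns `session_index`, `eta_hat`, `source`.
#' @export
forecast_eta <- function(hr_forecast, estimator, calibration) {
  if (!inherits(estimator, "eta_estimator")) {
    stop("invalid-argument: 'estimator' must be a trained eta_estimator")
  }
  stopifnot(inherits(calibration, "calibration_set"))
  sessions <- as.integer(names(hr_forecast))
  out <- lapply(seq_along(sessions), function(i) {
    s <- sessions[i]
    ci <- match(s, calibration$session_indices)
    if (!is.na(ci)) {
      data.frame(
        session_index = s, eta_hat = calibration$eta_values[ci],
        source = "calibration"
      )
    } else {
      X <- estimator_windows(estimator, hr_forecast[[i]])
      data.frame(
        session_index = s,
        eta_hat = unname(predict_session_eta(estimator, X)),
        source = "forecast"
      )
    }
  })
  do.call(rbind, out)
}

#' Predict ECG Lead II from Lead I
#'
#' Trains the sequence-to-sequence lead-reconstruction model on the
#' chronologically first `split_ratio` fraction of the paired leads and
#' evaluates it on the remainder. Both leads are normalized with
#' training-portion statistics; the validation prediction is mapped back to
#' physical units and scored with the normalized-RMSE fit percentage.
#'
#' @param lead1,lead2 Equal-length, equal-rate [sensor_stream()]s.
#' @param cfg A [lead_predict_config()].
#' @return A list of class `lead_predictor` with the trained model, the
#'   predicted validation-segment [sensor_stream()] (`predicted`), and the
#'   validation [metric_report()] (`report`).
#' @export
predict_lead2_from_lead1 <- function(lead1, lead2, cfg = lead_predict_config()) {
  stopifnot(is_sensor_stream(lead1), is_sensor_stream(lead2))
  if (nrow(lead1) != nrow(lead2)) {
    stop("invalid-argument: leads differ in length")
  }
  if (abs(attr(lead1, "fs") - attr(lead2, "fs")) > 1e-9) {
    stop("invalid-argument: leads differ in sampling rate")
  }
  n <- nrow(lead1)
  n_train <- floor(cfg$split_ratio * n)
  if (n_train < cfg$window || n - n_train < cfg$window) {
    stop("invalid-argument: record too short for the configured window/split")
  }
  x <- lead1$value; y <- lead2$value
  mx <- mean(x[1:n_train]); sx <- sqrt(mean((x[1:n_train] - mx)^2))
  my <- mean(y[1:n_train]); sy <- sqrt(mean((y[1:n_train] - my)^2))
  if (sx <= 0 || sy <= 0) stop("degenerate-input: zero variance in a lead")
  xn <- (x - mx) / sx; yn <- (y - my) / sy

  starts <- seq(1L, n_train - cfg$window + 1L, by = cfg$stride)
  idx <- outer(starts - 1L, seq_len(cfg$window), `+`)
  X <- array(matrix(xn[idx], nrow = length(starts)),
    c(length(starts), cfg$window, 1L)
  )
  Y <- array(matrix(yn[idx], nrow = length(starts)),
    c(length(starts), cfg$window, 1L)
  )
  model <- lstm_init(
    input_size = 1L, hidden_units = cfg$hidden_units, n_layers = cfg$n_layers,
    output_size = 1L, head = "seq", seed = cfg$seed
  )
  model <- lstm_train(model, X, Y,
    learning_rate = cfg$learning_rate, max_epochs = cfg$max_epochs,
    loss_tol = cfg$loss_tol
  )
  # validation: one pass over the held-out tail as a single long sequence
  val_idx <- (n_train + 1L):n
  Xv <- array(xn[val_idx], c(1L, length(val_idx), 1L))
  pred_n <- as.numeric(lstm_predict(model, Xv))
  pred <- pred_n * sy + my
  predicted <- sensor_stream(lead1$t_s[val_idx], pred,
    fs = attr(lead1, "fs"), channel = "ecg_lead2_pred", units = "mV"
  )
  structure(
    list(
      model = model, predicted = predicted,
      report = metric_report(y[val_idx], pred),
      norm = list(x = c(mx, sx), y = c(my, sy)), cfg = cfg,
      loss_history = attr(model, "loss_history")
    ),
    class = "lead_predictor"
  )
}
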