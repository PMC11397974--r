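#' Calibration set for sparse-measurement estimation
#'
#' Holds the sessions at which a direct device measurement of hysteresivity
#' is available (default sessions 1, 5 and 10 of a ten-session protocol:
#' three measurements anchor the whole record, a ten-to-three reduction) and
#' the measured eta value at each.
#'
#' @param session_indices 1-based calibration session indices.
#' @param eta_values Measured hysteresivity per calibration session (one
#'   device band at a time).
#' @return A list of class `calibration_set`.
#' @export
calibration_set <- function(session_indices = c(1L, 5L, 10L), eta_values) {
  if (length(session_indices) != length(eta_values)) {
    stop("invalid-argument: one measured eta per calibration session required")
  }
  if (anyDuplicated(session_indices)) {
    stop("invalid-argument: duplicated calibration session indices")
  }
  if (any(session_indices < 1)) {
    stop("invalid-argument: session indices are 1-based")
  }
  structure(
    list(
      session_indices = as.integer(session_indices),
      eta_values = as.numeric(eta_values)
    ),
    class = "calibration_set"
  )
}

#' Estimator sequence-model configuration
#'
#' Defaults follow the estimation architecture: a single LSTM layer of 50
#' hidden units, a fully connected regression head, input windows of 60
#' samples (1 min of 1-Hz heart rate), Adam with learning rate 0.01 for at
#' most 200 epochs with a 20-epoch early-stopping plateau.
#'
#' @param hidden_units LSTM width (default 50).
#' @param n_layers Number of LSTM layers (default 1).
#' @param input_window Window length in samples (default 60).
#' @param max_epochs Maximum training epochs (default 200).
#' @param learning_rate Adam step size (default 0.01).
#' @param split_ratio Chronological train fraction where a split is used
#'   (default 0.7).
#' @param loss_tol Convergence floor on the training MSE of the normalized
#'   labels (default 5e-4); see [lstm_train()].
#' @param seed Integer seed fixing initialization (training is full-batch,
#'   hence otherwise deterministic).
#' @return A list of class `sequence_model_config`.
#' @export
sequence_model_config <- function(hidden_units = 50L, n_layers = 1L,
                                  input_window = 60L, max_epochs = 200L,
                                  learning_rate = 0.01, split_ratio = 0.7,
                                  loss_tol = 5e-4, seed = 1L) {
  if (hidden_units < 1) stop("invalid-argument: 'hidden_units' must be >= 1")
  if (split_ratio <= 0 || split_ratio >= 1) {
    stop("invalid-argument: 'split_ratio' must lie in (0, 1)")
  }
  structure(
    list(
      hidden_units = as.integer(hidden_units), n_layers = as.integer(n_layers),
      input_window = as.integer(input_window), max_epochs = as.integer(max_epochs),
      learning_rate = learning_rate, split_ratio = split_ratio,
      loss_tol = loss_tol, seed = as.integer(seed)
    ),
    class = "sequence_model_config"
  )
}

# Sliding stride-1 windows of one session's sample vector: (len - window + 1)
# rows of length `window`.
sliding_windows <- function(x, window) {
  n <- length(x) - window + 1L
  if (n < 1L) return(NULL)
  idx <- outer(seq_len(n) - 1L, seq_len(window), `+`)
  matrix(x[idx], nrow = n)
}

#' Prepare training and inference sequences from per-session HR segments
#'
#' Training pairs are all overlapping stride-1 sub-windows of the
#' calibration sessions' HR segments, each labelled with that session's
#' measured eta (sub-window augmentation is what makes a sequence model
#' trainable from three labelled sessions). Inference inputs are the same
#' windowing applied to the remaining sessions. Input and label
#' normalization parameters are fitted on the training data only and stored
#' for the inverse mapping of predictions.
#'
#' @param hr_segments List of per-session HR [sensor_stream()] segments (one
#'   per session, with `session_index` attributes), e.g. from
#'   [align_stream()].
#' @param calibration A [calibration_set()].
#' @param cfg A [sequence_model_config()].
#' @return A list of class `eta_sequences` with `train` (array `X`, labels
#'   `y`), `infer` (per-session window arrays), and the stored normalization
#'   parameters.
#' @export
prepare_sequences <- function(hr_segments, calibration,
                              cfg = sequence_model_config()) {
  sessions <- vapply(seq_along(hr_segments), function(i) {
    si <- attr(hr_segments[[i]], "session_index")
    if (is.null(si)) i else as.integer(si)
  }, integer(1))
  if (!all(calibration$session_indices %in% sessions)) {
    stop("invalid-argument: calibration sessions missing from the segment list")
  }
  win_by_session <- lapply(seq_along(hr_segments), function(i) {
    w <- sliding_windows(hr_segments[[i]]$value, cfg$input_window)
    if (is.null(w)) {
      stop(sprintf(
        "invalid-argument: session %d segment (%d samples) shorter than input_window (%d)",
        sessions[i], nrow(hr_segments[[i]]), cfg$input_window
      ))
    }
    w
  })
  names(win_by_session) <- as.character(sessions)
  is_cal <- sessions %in% calibration$session_indices
  train_mat <- do.call(rbind, win_by_session[is_cal])
  train_lab <- unlist(lapply(which(is_cal), function(i) {
    eta <- calibration$eta_values[
      match(sessions[i], calibration$session_indices)
    ]
    rep(eta, nrow(win_by_session[[i]]))
  }))
  x_mean <- mean(train_mat)
  x_sd <- sqrt(mean((train_mat - x_mean)^2))
  if (x_sd <= 0) x_sd <- 1
  y_mean <- mean(calibration$eta_values)
  y_sd <- sqrt(mean((calibration$eta_values - y_mean)^2))
  if (y_sd <= 0) y_sd <- 1
  to_array <- function(m) {
    array((m - x_mean) / x_sd, c(nrow(m), ncol(m), 1L))
  }
  structure(
    list(
      train = list(
        X = to_array(train_mat),
        y = (train_lab - y_mean) / y_sd,
        sessions = sessions[is_cal]
      ),
      infer = lapply(win_by_session, to_array),
      sessions = sessions,
      calibration = calibration,
      x_norm = c(mean = x_mean, sd = x_sd),
      y_norm = c(mean = y_mean, sd = y_sd),
      cfg = cfg
    ),
    class = "eta_sequences"
  )
}

#' Train the eta estimator on calibration sequences
#'
#' Fits the recurrent sequence model (LSTM + linear regression head) to the
#' prepared calibration windows by full-batch Adam on mean squared error.
#'
#' @param prepared An [prepare_sequences()] result.
#' @param cfg A [sequence_model_config()] (defaults to the one stored in
#'   `prepared`).
#' @return A list of class `eta_estimator` carrying the trained model and
#'   the normalization parameters; the training-loss trajectory is in
#'   `$loss_history`.
#' @export
train_estimator <- function(prepared, cfg = prepared$cfg) {
  stopifnot(inherits(prepared, "eta_sequences"))
  if (length(prepared$train$y) == 0L) {
    stop("invalid-argument: empty training set")
  }
  model <- lstm_init(
    input_size = 1L, hidden_units = cfg$hidden_units,
    n_layers = cfg$n_layers, output_size = 1L, head = "last",
    seed = cfg$seed
  )
  model <- lstm_train(model, prepared$train$X,
    matrix(prepared$train$y, ncol = 1L),
    learning_rate = cfg$learning_rate, max_epochs = cfg$max_epochs,
    loss_tol = if (is.null(cfg$loss_tol)) 0 else cfg$loss_tol
  )
  structure(
    list(
      model = model,
      x_norm = prepared$x_norm, y_norm = prepared$y_norm, cfg = cfg,
      loss_history = attr(model, "loss_history")
    ),
    class = "eta_estimator"
  )
}

# Model-path eta for one session: mean of the window-level predictions,
# mapped back through the label normalization.
predict_session_eta <- function(estimator, X) {
  pred <- lstm_predict(estimator$model, X)
  mean(pred) * estimator$y_norm["sd"] + estimator$y_norm["mean"]
}

# Window a raw per-session HR vector with the estimator's stored input
# normalization (used by both the estimation and the forecasting path, so
# an error-free HR forecast reproduces the estimation path exactly).
estimator_windows <- function(estimator, hr_values) {
  w <- sliding_windows(hr_values, estimator$cfg$input_window)
  if (is.null(w)) {
    stop("invalid-argument: HR sequence shorter than the estimator input window")
  }
  array((w - estimator$x_norm["mean"]) / estimator$x_norm["sd"],
    c(nrow(w), ncol(w), 1L)
  )
}

#' Estimate per-session eta from prepared sequences
#'
#' Calibration sessions pass through their measured value (`source =
#' "calibration"`); every other session receives the mean of the model's
#' window-level predictions mapped back to the eta scale (`source =
#' "model"`).
#'
#' @param estimator A trained [train_estimator()] result.
#' @param prepared The [prepare_sequences()] result for the record.
#' @param calibration A [calibration_set()] (defaults to the one stored in
#'   `prepared`).
#' @return A data frame with columns `session_index`, `eta_hat`, `source`.
#' @export
estimate_eta <- function(estimator, prepared,
                         calibration = prepared$calibration) {
  stopifnot(inherits(estimator, "eta_estimator"))
  sessions <- prepared$sessions
  missing_cal <- setdiff(calibration$session_indices, sessions)
  if (length(missing_cal)) {
    stop(sprintf(
      "coverage error: no segment for calibration session(s) %s",
      paste(missing_cal, collapse = ", ")
    ))
  }
  out <- lapply(seq_along(sessions), function(i) {
    s <- sessions[i]
    ci <- match(s, calibration$session_indices)
    if (!is.na(ci)) {
      data.frame(
        session_index = s, eta_hat = calibration$eta_values[ci],
        source = "calibration"
      )
    } else {
      data.frame(
        session_index = s,
        eta_hat = unname(predict_session_eta(
          estimator, prepared$infer[[as.character(s)]]
        )),
        source = "model"
      )
    }
  })
  do.call(rbind, out)
}
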