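#' Full-pipeline run configuration
#'
#' One configuration object drives the whole analysis: synthetic cohort
#' generation, protocol construction, impedance identification, sparse-
#' calibration estimation, dual-step forecasting and evaluation. Every
#' randomized stage receives a seed derived deterministically from the
#' global `seed`, so a rerun with the same configuration is reproducible.
#' Unknown keys in `...` raise a validation error naming the key.
#'
#' @param n_subjects Number of synthetic subjects (default 1).
#' @param seed Global integer seed (default 1).
#' @param bands Device bands to process (default both `"low"` and
#'   `"high"`).
#' @param calibration_sessions Sessions with direct measurements (default
#'   `c(1, 5, 10)`).
#' @param protocol,generator,estimator,forecaster,metrics Named lists
#'   overriding stage defaults (see the corresponding constructors).
#' @param ... Rejected; present to catch misspelled keys.
#' @return A list of class `run_config`.
#' @export
run_config <- function(n_subjects = 1L, seed = 1L,
                       bands = c("low", "high"),
                       calibration_sessions = c(1L, 5L, 10L),
                       protocol = list(), generator = list(),
                       estimator = list(), forecaster = list(),
                       metrics = list(), ...) {
  extra <- list(...)
  if (length(extra)) {
    stop(
      "validation error: unknown configuration key(s): ",
      paste(names(extra), collapse = ", ")
    )
  }
  merge_cfg <- function(defaults, user, stage) {
    bad <- setdiff(names(user), names(defaults))
    if (length(bad)) {
      stop(sprintf(
        "validation error: unknown key(s) in '%s': %s",
        stage, paste(bad, collapse = ", ")
      ))
    }
    utils::modifyList(defaults, user)
  }
  structure(
    list(
      n_subjects = as.integer(n_subjects), seed = as.integer(seed),
      bands = match.arg(bands, c("low", "high"), several.ok = TRUE),
      calibration_sessions = as.integer(calibration_sessions),
      protocol = merge_cfg(
        list(n_sessions = 10L, fot_min = 2, rest_min = 5, resmon_min = 1),
        protocol, "protocol"
      ),
      generator = merge_cfg(
        list(
          coupling_gamma = 1, noise_sd_eta = 0.12, ecg_fs = 256,
          fot_noise_sd = 0.02, breathing_frac = 0.2
        ),
        generator, "generator"
      ),
      estimator = merge_cfg(
        list(
          hidden_units = 50L, n_layers = 1L, input_window = 60L,
          max_epochs = 200L, learning_rate = 0.01
        ),
        estimator, "estimator"
      ),
      forecaster = merge_cfg(
        list(
          hidden_units = 150L, n_layers = 2L, max_epochs = 200L,
          learning_rate = 0.01, split_ratio = 0.7
        ),
        forecaster, "forecaster"
      ),
      metrics = merge_cfg(list(method = "t"), metrics, "metrics")
    ),
    class = "run_config"
  )
}

#' Read and write run configurations as JSON
#'
#' @param config A [run_config()].
#' @param path JSON file path.
#' @return `write_run_config` returns `path` invisibly; `read_run_config`
#'   returns a validated [run_config()] (lossless round trip).
#' @export
write_run_config <- function(config, path) {
  stopifnot(inherits(config, "run_config"))
  jsonlite::write_json(unclass(config), path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_run_config
#' @export
read_run_config <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  do.call(run_config, x)
}

# Process one subject for one band: impedance identification at the
# calibration and reference sessions, estimator training, estimation and
# dual-step forecasting. Returns estimates, forecasts and metric reports.
run_subject_band <- function(session, hr_segments, hr_ecg_segments, band,
                             config, est_seed, fc_seed) {
  n_sessions <- session$timeline$n_sessions
  eta_measured <- vapply(seq_len(n_sessions), function(k) {
    rec <- session$fot[[band]][[k]]
    sp <- estimate_spectrum(rec$pressure, rec$flow, rec$grid, rec$fs,
      band = band, session_index = k
    )
    fit_constant_phase(sp)$eta
  }, numeric(1))
  calib <- calibration_set(
    config$calibration_sessions,
    eta_measured[config$calibration_sessions]
  )
  est_cfg <- sequence_model_config(
    hidden_units = config$estimator$hidden_units,
    n_layers = config$estimator$n_layers,
    input_window = config$estimator$input_window,
    max_epochs = config$estimator$max_epochs,
    learning_rate = config$estimator$learning_rate,
    seed = est_seed
  )
  prepared <- prepare_sequences(hr_segments, calib, est_cfg)
  est <- train_estimator(prepared)
  estimates <- estimate_eta(est, prepared)

  fc_cfg <- forecast_config(
    hidden_units = config$forecaster$hidden_units,
    n_layers = config$forecaster$n_layers,
    horizon_min = if (band == "low") 11 else 12,
    max_epochs = config$forecaster$max_epochs,
    learning_rate = config$forecaster$learning_rate,
    split_ratio = config$forecaster$split_ratio,
    seed = fc_seed
  )
  forecaster <- train_hr_forecaster(hr_ecg_segments, fc_cfg)
  hr_fc <- forecast_hr(forecaster, hr_ecg_segments)
  forecasts <- forecast_eta(hr_fc, est, calib)

  truth <- session$true_eta
  est_model <- estimates[estimates$source == "model", ]
  fc_model <- forecasts[forecasts$source == "forecast", ]
  list(
    band = band,
    eta_measured = eta_measured,
    estimates = estimates,
    forecasts = forecasts,
    metrics = list(
      estimation = metric_report(
        truth[est_model$session_index], est_model$eta_hat,
        method = config$metrics$method
      ),
      forecast = metric_report(
        truth[fc_model$session_index], fc_model$eta_hat,
        method = config$metrics$method
      )
    )
  )
}

#' Run the complete analysis pipeline
#'
#' Executes, for each synthetic subject: session generation (streams, ECG,
#' per-session constant-phase parameters, FOT records in both bands),
#' impedance identification of the measured eta per session, estimator
#' training on the calibration sessions' HR windows, per-session eta
#' estimation, ECG-derived HR forecasting and dual-step eta forecasting,
#' and metric evaluation against the generator's ground truth. When
#' `out_dir` is given, all intermediate artifacts (stream CSVs, FOT CSVs,
#' estimate/forecast CSVs, metric JSONs) and a run manifest are written.
#'
#' @param config A [run_config()].
#' @param out_dir Output directory, or `NULL` to skip writing artifacts.
#' @return The run manifest (list), invisibly when writing.
#' @export
run_pipeline <- function(config = run_config(), out_dir = NULL) {
  stopifnot(inherits(config, "run_config"))
  timeline <- do.call(build_timeline, config$protocol)
  profiles <- sample_subject_profiles(
    config$n_subjects,
    seed = config$seed,
    coupling_gamma = config$generator$coupling_gamma,
    noise_sd_eta = config$generator$noise_sd_eta
  )
  windows <- eqv_extraction_windows(timeline)
  subjects <- lapply(seq_along(profiles), function(i) {
    profile <- profiles[[i]]
    session <- synthetic_session(profile, timeline,
      ecg_fs = config$generator$ecg_fs,
      fot_noise_sd = config$generator$fot_noise_sd,
      breathing_frac = config$generator$breathing_frac
    )
    hr_clean <- preprocess_stream(session$streams$hr)
    hr_segments <- align_stream(hr_clean, windows)
    hr_ecg_segments <- derive_hr_input(
      list(lead1 = session$streams$ecg_lead1, lead2 = session$streams$ecg_lead2),
      timeline
    )
    bands <- lapply(config$bands, function(b) {
      run_subject_band(
        session, hr_segments, hr_ecg_segments, b, config,
        est_seed = derive_seed(config$seed, 1000L + i),
        fc_seed = derive_seed(config$seed, 2000L + i)
      )
    })
    names(bands) <- config$bands
    if (!is.null(out_dir)) {
      sdir <- file.path(out_dir, profile$subject_id)
      write_session(session, sdir)
      for (b in config$bands) {
        utils::write.csv(
          transform(bands[[b]]$estimates, band = b),
          file.path(sdir, sprintf("estimates_%s.csv", b)),
          row.names = FALSE, quote = FALSE
        )
        utils::write.csv(
          transform(bands[[b]]$forecasts,
            band = b,
            horizon_min = if (b == "low") 11 else 12
          ),
          file.path(sdir, sprintf("forecasts_%s.csv", b)),
          row.names = FALSE, quote = FALSE
        )
        jsonlite::write_json(
          lapply(bands[[b]]$metrics, unclass),
          file.path(sdir, sprintf("metrics_%s.json", b)),
          auto_unbox = TRUE, digits = NA
        )
      }
    }
    list(
      subject_id = profile$subject_id,
      true_eta = session$true_eta,
      n_sessions = timeline$n_sessions,
      n_calibration = length(config$calibration_sessions),
      n_estimated = sum(bands[[1L]]$estimates$source == "model"),
      n_forecast = sum(bands[[1L]]$forecasts$source == "forecast"),
      bands = bands
    )
  })
  manifest <- list(
    config = unclass(config),
    timeline = list(
      n_sessions = timeline$n_sessions,
      total_duration = timeline$total_duration
    ),
    subjects = lapply(subjects, function(s) {
      c(
        s[c("subject_id", "n_sessions", "n_calibration", "n_estimated", "n_forecast")],
        list(metrics = lapply(s$bands, function(b) lapply(b$metrics, unclass)))
      )
    })
  )
  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
      auto_unbox = TRUE, digits = NA
    )
  }
  invisible(list(manifest = manifest, subjects = subjects))
}
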