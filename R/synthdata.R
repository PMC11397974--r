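#' Synthetic subject profile
#'
#' Describes one simulated subject: biometrics (mirroring the cohort-style
#' metadata of a small healthy adult study), a baseline heart rate, a
#' baseline tissue hysteresivity, and the parameters of the stochastic
#' coupling by which session-level hysteresivity follows heart rate. The
#' `seed` fixes all randomness for the subject, so regeneration is
#' bit-identical.
#'
#' @param subject_id Subject label.
#' @param age Age in years.
#' @param weight Weight in kg.
#' @param height Height in cm.
#' @param hr_baseline Baseline heart rate in beats/min, in `[40, 180]`.
#' @param eta_baseline Baseline hysteresivity, `> 0`.
#' @param coupling_gamma Relative change in eta per relative change in HR
#'   (dimensionless; default 1).
#' @param noise_sd_eta SD of the session-level additive eta noise.
#' @param seed Integer seed fixing all of the subject's randomness.
#' @param bmi Body-mass index; computed from weight/height when omitted and
#'   checked for consistency (within 0.5 kg/m^2) when given.
#' @return A list of class `subject_profile`.
#' @examples
#' p <- subject_profile("S1", age = 30, weight = 70, height = 175,
#'                      hr_baseline = 70, eta_baseline = 1.2, seed = 1)
#' p$bmi
#' @export
subject_profile <- function(subject_id, age, weight, height, hr_baseline,
                            eta_baseline, coupling_gamma = 1,
                            noise_sd_eta = 0.12, seed = 1L, bmi = NULL) {
  bmi_calc <- weight / (height / 100)^2
  if (is.null(bmi)) {
    bmi <- bmi_calc
  } else if (abs(bmi - bmi_calc) > 0.5) {
    stop("invalid-argument: 'bmi' inconsistent with weight/height^2 by more than 0.5")
  }
  if (hr_baseline < 40 || hr_baseline > 180) {
    stop("invalid-argument: 'hr_baseline' must lie in [40, 180]")
  }
  if (eta_baseline <= 0) stop("invalid-argument: 'eta_baseline' must be positive")
  if (noise_sd_eta < 0) stop("invalid-argument: 'noise_sd_eta' must be non-negative")
  structure(
    list(
      subject_id = as.character(subject_id), age = age, weight = weight,
      height = height, bmi = bmi, hr_baseline = hr_baseline,
      eta_baseline = eta_baseline, coupling_gamma = coupling_gamma,
      noise_sd_eta = noise_sd_eta, seed = as.integer(seed)
    ),
    class = "subject_profile"
  )
}

#' @export
print.subject_profile <- function(x, ...) {
  cat(sprintf(
    "<subject_profile '%s'> age %g, BMI %.1f, HR0 %g bpm, eta0 %.3g (gamma %.2g, sd %.3g), seed %d\n",
    x$subject_id, x$age, x$bmi, x$hr_baseline, x$eta_baseline,
    x$coupling_gamma, x$noise_sd_eta, x$seed
  ))
  invisible(x)
}

#' Draw a cohort of synthetic subject profiles
#'
#' Biometrics are drawn to resemble a small healthy adult cohort (ages
#' ~28-40, BMI ~19-28). Baseline hysteresivity varies between subjects
#' (normal, mean 1.3, SD 0.5, truncated to `[0.3, 2.8]`), which is what
#' makes pooled estimation informative: within a subject the HR coupling is
#' moderate by design, while subject-to-subject differences in baseline eta
#' dominate the pooled variance.
#'
#' @param n Number of subjects.
#' @param seed Integer seed; subject `i` receives the derived seed for all
#'   of its own randomness.
#' @param coupling_gamma,noise_sd_eta Coupling defaults passed to every
#'   profile.
#' @return A list of [subject_profile()]s.
#' @export
sample_subject_profiles <- function(n, seed = 1L, coupling_gamma = 1,
                                    noise_sd_eta = 0.12) {
  stopifnot(n >= 1)
  with_seed(derive_seed(seed, 0L), {
    lapply(seq_len(n), function(i) {
      subject_profile(
        subject_id = sprintf("S%02d", i),
        age = round(stats::runif(1, 25, 45)),
        weight = round(stats::runif(1, 50, 95)),
        height = round(stats::runif(1, 158, 185)),
        hr_baseline = min(max(stats::rnorm(1, 72, 8), 55), 95),
        eta_baseline = min(max(stats::rnorm(1, 1.3, 0.5), 0.3), 2.8),
        coupling_gamma = coupling_gamma,
        noise_sd_eta = noise_sd_eta,
        seed = derive_seed(seed, i)
      )
    })
  })
}

#' Generate a continuous heart-rate profile
#'
#' Produces an HR series at `fs` samples/s (default 1 Hz) over `duration`
#' seconds: baseline + slow drift + short-term variability, clipped to
#' `[40, 180]` beats/min. The drift is a Gaussian random walk smoothed to a
#' > 5-min timescale (moving-average window 600 s) and rescaled to SD
#' `drift_sd` over the record, so the drift amplitude is controlled exactly;
#' the short-term component is white with SD `noise_sd`.
#'
#' @param duration Record length in seconds, `> 0`.
#' @param profile A [subject_profile()]; its seed fixes the realization.
#' @param fs Sampling rate in Hz (default 1).
#' @param drift_sd SD of the slow drift component in beats/min (default 3).
#' @param noise_sd SD of the sample-to-sample variability (default 1.5).
#' @return A [sensor_stream()] with channel `"hr"`.
#' @export
generate_hr_profile <- function(duration, profile, fs = 1, drift_sd = 3,
                                noise_sd = 1.5) {
  if (!is.numeric(duration) || duration <= 0) {
    stop("invalid-argument: 'duration' must be positive")
  }
  n <- floor(duration * fs)
  win <- max(1L, as.integer(600 * fs)) # 10-min moving average -> >5-min timescale
  with_seed(derive_seed(profile$seed, 1L), {
    drift <- numeric(n)
    if (drift_sd > 0) {
      pad <- win
      walk <- cumsum(stats::rnorm(n + 2L * pad))
      sm <- stats::filter(walk, rep(1 / win, win), sides = 2L)
      sm <- as.numeric(sm)[(pad + 1L):(pad + n)]
      s <- stats::sd(sm)
      drift <- if (s > 0) (sm - mean(sm)) / s * drift_sd else numeric(n)
    }
    noise <- if (noise_sd > 0) stats::rnorm(n, 0, noise_sd) else numeric(n)
    hr <- pmin(pmax(profile$hr_baseline + drift + noise, 40), 180)
    sensor_stream((seq_len(n) - 1L) / fs, hr,
      fs = fs, channel = "hr", units = "bpm"
    )
  })
}

#' ECG lead transform
#'
#' The second lead is generated from the same beat sequence as the first by
#' reweighting the P/QRS/T kernel amplitudes (`kernel_gain`), applying an
#' affine map (`scale`, `offset`) and adding independent noise. The identity
#' transform (all gains 1, scale 1, offset 0) makes Lead II identical to
#' Lead I at zero noise.
#'
#' @param kernel_gain Length-3 multiplier for the P, QRS and T kernel
#'   amplitudes.
#' @param scale,offset Affine map applied to the morphed waveform.
#' @return A list of class `lead_transform`.
#' @export
lead_transform <- function(kernel_gain = c(1.4, 1.7, 1.2), scale = 1,
                           offset = 0.05) {
  stopifnot(length(kernel_gain) == 3L)
  structure(list(kernel_gain = kernel_gain, scale = scale, offset = offset),
    class = "lead_transform"
  )
}

#' @rdname lead_transform
#' @export
identity_lead_transform <- function() {
  lead_transform(kernel_gain = c(1, 1, 1), scale = 1, offset = 0)
}

# P/QRS/T Gaussian kernel template for one beat, relative to the R peak.
# Columns: center offset (s), width (s), Lead I amplitude (mV).
ecg_template <- function() {
  cbind(
    center = c(-0.16, 0, 0.30),
    width = c(0.035, 0.022, 0.070),
    amp = c(0.12, 1.0, 0.30)
  )
}

#' Synthesize a two-lead ECG from a heart-rate profile
#'
#' Lead I is built beat by beat as a sum of three Gaussian kernels (P wave,
#' QRS complex, T wave) placed at beat times obtained by integrating the
#' instantaneous heart rate; Lead II applies a fixed [lead_transform()] to
#' the same beat sequence plus independent noise.
#'
#' @param hr A [sensor_stream()] of heart rate in beats/min (all positive).
#' @param transform A [lead_transform()] mapping Lead I morphology to
#'   Lead II.
#' @param seed Integer seed for the additive noise.
#' @param fs ECG sampling rate in Hz (default 256).
#' @param noise_sd SD of the additive white noise on each lead, in mV
#'   (default 0.02).
#' @return A list with [sensor_stream()]s `lead1` and `lead2` and the vector
#'   `beat_times` (s) of R-peak locations.
#' @export
generate_ecg <- function(hr, transform = lead_transform(), seed = 1L,
                         fs = 256, noise_sd = 0.02) {
  stopifnot(is_sensor_stream(hr))
  if (nrow(hr) == 0L) stop("invalid-argument: empty HR stream")
  if (any(hr$value <= 0)) stop("invalid-argument: HR values must be positive")
  t0 <- hr$t_s[1L]
  t1 <- hr$t_s[nrow(hr)] + 1 / attr(hr, "fs")
  hr_at <- stats::approxfun(hr$t_s, hr$value, rule = 2L)
  # beat times by stepping through RR intervals from the instantaneous HR
  beats <- numeric(ceiling((t1 - t0) / (60 / 180)) + 2L)
  nb <- 0L
  tb <- t0
  while (tb < t1) {
    nb <- nb + 1L
    beats[nb] <- tb
    tb <- tb + 60 / hr_at(tb)
  }
  beats <- beats[seq_len(nb)]

  n <- floor((t1 - t0) * fs)
  tt <- t0 + (seq_len(n) - 1L) / fs
  tpl <- ecg_template()
  amps2 <- tpl[, "amp"] * transform$kernel_gain
  lead1 <- numeric(n)
  lead2m <- numeric(n)
  half <- ceiling(0.45 * fs) # kernel support half-width in samples
  for (b in beats) {
    ic <- floor((b - t0) * fs) + 1L
    lo <- max(1L, ic - half)
    hi <- min(n, ic + half)
    if (lo > hi) next
    dt <- tt[lo:hi] - b
    for (k in 1:3) {
      kern <- exp(-0.5 * ((dt - tpl[k, "center"]) / tpl[k, "width"])^2)
      lead1[lo:hi] <- lead1[lo:hi] + tpl[k, "amp"] * kern
      lead2m[lo:hi] <- lead2m[lo:hi] + amps2[k] * kern
    }
  }
  lead2 <- transform$scale * lead2m + transform$offset
  with_seed(derive_seed(seed, 2L), {
    if (noise_sd > 0) {
      lead1 <- lead1 + stats::rnorm(n, 0, noise_sd)
      lead2 <- lead2 + stats::rnorm(n, 0, noise_sd)
    }
    list(
      lead1 = sensor_stream(tt, lead1, fs = fs, channel = "ecg_lead1", units = "mV"),
      lead2 = sensor_stream(tt, lead2, fs = fs, channel = "ecg_lead2", units = "mV"),
      beat_times = beats
    )
  })
}

#' Generate per-session constant-phase parameters coupled to heart rate
#'
#' Realizes the moderate HR-hysteresivity coupling: for session `k` with
#' session-mean heart rate `HR_k`,
#' \deqn{\eta_k = \eta_0\,(1 + \gamma\,(HR_k - HR_0)/HR_0) + \varepsilon_k,
#'   \quad \varepsilon_k \sim N(0, \sigma_\varepsilon^2),}
#' with `eta_0 = profile$eta_baseline`, `HR_0 = profile$hr_baseline`,
#' `gamma = profile$coupling_gamma` and
#' `sigma_eps = profile$noise_sd_eta`. Airway resistance, inertance and the
#' tissue magnitude `D` are drawn once per subject with small (2\%) relative
#' per-session jitter; the exponent `alpha` is back-computed from `eta_k` via
#' `alpha = (2/pi) atan(1/eta)`.
#'
#' @param profile A [subject_profile()].
#' @param hr_per_session Session-mean heart rates in beats/min.
#' @param n_sessions Number of sessions (defaults to
#'   `length(hr_per_session)`).
#' @return A list of [constant_phase_params()], one per session, each with a
#'   `session_index` attribute.
#' @export
generate_session_params <- function(profile, hr_per_session,
                                    n_sessions = length(hr_per_session)) {
  if (n_sessions < 1) stop("invalid-argument: 'n_sessions' must be >= 1")
  if (length(hr_per_session) != n_sessions) {
    stop("invalid-argument: need one session-mean HR per session")
  }
  with_seed(derive_seed(profile$seed, 3L), {
    R0 <- max(stats::rnorm(1, 3, 0.5), 0.5)
    L0 <- max(stats::rnorm(1, 0.01, 0.002), 0.001)
    D0 <- max(stats::rnorm(1, 5, 1), 1)
    eps <- if (profile$noise_sd_eta > 0) {
      stats::rnorm(n_sessions, 0, profile$noise_sd_eta)
    } else {
      numeric(n_sessions)
    }
    jit <- matrix(stats::rnorm(3L * n_sessions, 0, 0.02), nrow = n_sessions)
    lapply(seq_len(n_sessions), function(k) {
      eta_k <- profile$eta_baseline *
        (1 + profile$coupling_gamma *
          (hr_per_session[k] - profile$hr_baseline) / profile$hr_baseline) +
        eps[k]
      eta_k <- max(eta_k, 0.05) # hysteresivity is positive by definition
      p <- constant_phase_params(
        R = R0 * (1 + jit[k, 1L]),
        L = L0 * (1 + jit[k, 2L]),
        D = D0 * (1 + jit[k, 3L]),
        alpha = alpha_from_eta(eta_k)
      )
      attr(p, "session_index") <- k
      p
    })
  })
}

#' Synthesize multisine forced-oscillation pressure and flow
#'
#' Pressure is a multisine over the band's excitation grid (random phases,
#' equal component amplitudes, unit RMS, an integer number of periods of
#' every component in the record). Flow is the exact frequency-wise
#' inverse-model response `Q(f) = P(f)/Z(j 2 pi f)` for the given
#' constant-phase parameters, plus a breathing component (sinusoid at
#' 0.25 Hz, amplitude a fraction of the excitation-flow RMS) and white
#' noise on both channels.
#'
#' @param params A [constant_phase_params()] set generating the response.
#' @param band `"low"` (0.2-2 Hz, default duration 120 s, fs 100 Hz) or
#'   `"high"` (5-37 Hz, default duration 60 s, fs 200 Hz).
#' @param duration Record length in seconds (band default when `NULL`).
#' @param fs Sampling rate in Hz (band default when `NULL`).
#' @param noise_sd SD of additive white pressure noise in cmH2O (flow noise
#'   is scaled by the flow/pressure RMS ratio); default 0.02.
#' @param breathing_frac Breathing-flow amplitude as a fraction of the
#'   excitation-flow RMS (default 0.2; 0 disables it).
#' @param seed Integer seed for phases and noise.
#' @return A list of class `fot_record`: `t_s`, `pressure`, `flow`, `grid`,
#'   `band`, `fs`, `seed`, `true_params`.
#' @export
generate_fot_signals <- function(params, band = c("low", "high"),
                                 duration = NULL, fs = NULL, noise_sd = 0.02,
                                 breathing_frac = 0.2, seed = 1L) {
  band <- match.arg(band)
  grid <- band_grid(band)
  if (is.null(duration)) duration <- if (band == "low") 120 else 60
  if (is.null(fs)) fs <- if (band == "low") 100 else 200
  if (fs <= 2 * max(grid)) {
    stop("invalid-argument: fs must exceed twice the highest grid frequency")
  }
  n <- floor(duration * fs)
  tt <- (seq_len(n) - 1L) / fs
  nf <- length(grid)
  amp <- sqrt(2 / nf) # unit total pressure RMS
  with_seed(derive_seed(seed, 4L), {
    phases <- stats::runif(nf, 0, 2 * pi)
    zf <- constant_phase_impedance(grid, params)
    pressure <- numeric(n)
    flow <- numeric(n)
    for (i in seq_len(nf)) {
      pf <- amp * exp(1i * phases[i])
      e <- exp(1i * 2 * pi * grid[i] * tt)
      pressure <- pressure + Re(pf * e)
      flow <- flow + Re(pf / zf[i] * e)
    }
    rms_q <- sqrt(mean(flow^2))
    if (breathing_frac > 0) {
      flow <- flow + breathing_frac * rms_q * sin(2 * pi * 0.25 * tt)
    }
    if (noise_sd > 0) {
      pressure <- pressure + stats::rnorm(n, 0, noise_sd)
      flow <- flow + stats::rnorm(n, 0, noise_sd * max(rms_q, 1e-12))
    }
    structure(
      list(
        t_s = tt, pressure = pressure, flow = flow, grid = grid,
        band = band, fs = fs, seed = as.integer(seed), true_params = params
      ),
      class = "fot_record"
    )
  })
}

#' @export
print.fot_record <- function(x, ...) {
  cat(sprintf(
    "<fot_record> band '%s', %d samples @ %g Hz, %d excitation frequencies\n",
    x$band, length(x$t_s), x$fs, length(x$grid)
  ))
  invisible(x)
}

#' Generate a complete synthetic subject session
#'
#' Drives every generator for one subject over a full protocol: continuous
#' HR, RR and skin-temperature streams spanning the timeline, a two-lead ECG
#' synthesized from the HR profile, per-session constant-phase parameters
#' whose hysteresivity is stochastically coupled to the session-mean HR, and
#' per-session multisine FOT pressure/flow records in both bands. Everything
#' is reproducible from the profile's seed.
#'
#' @param profile A [subject_profile()].
#' @param timeline A [build_timeline()] result (default protocol).
#' @param with_ecg,with_fot Generate the ECG leads / the FOT records
#'   (disable to cut cost when only the HR path is exercised).
#' @param ecg_fs ECG sampling rate in Hz.
#' @param fot_noise_sd,breathing_frac Passed to [generate_fot_signals()].
#' @return A list of class `synthetic_session`: `profile`, `timeline`,
#'   `streams` (named list), `true_params` (per session), `true_eta`
#'   (numeric per session), `hr_session_means`, and `fot` (per band, per
#'   session) when requested.
#' @export
synthetic_session <- function(profile, timeline = build_timeline(),
                              with_ecg = TRUE, with_fot = TRUE,
                              ecg_fs = 256, fot_noise_sd = 0.02,
                              breathing_frac = 0.2) {
  duration <- timeline$total_duration * 60
  hr <- generate_hr_profile(duration, profile)
  windows <- eqv_extraction_windows(timeline)
  hr_segments <- align_stream(hr, windows)
  hr_means <- vapply(hr_segments, function(s) mean(s$value), numeric(1))
  true_params <- generate_session_params(profile, hr_means)
  true_eta <- vapply(true_params, `[[`, numeric(1), "eta")

  streams <- list(hr = hr)
  with_seed(derive_seed(profile$seed, 5L), {
    n_slow <- floor(duration * 0.2)
    t_slow <- (seq_len(n_slow) - 1L) / 0.2
    streams$rr <- sensor_stream(
      t_slow, pmax(stats::rnorm(n_slow, 15, 1), 6),
      fs = 0.2, channel = "rr", units = "breaths/min"
    )
    streams$st <- sensor_stream(
      t_slow, 33 + cumsum(stats::rnorm(n_slow, 0, 0.01)),
      fs = 0.2, channel = "st", units = "degC"
    )
  })
  if (with_ecg) {
    ecg <- generate_ecg(hr, seed = profile$seed, fs = ecg_fs)
    streams$ecg_lead1 <- ecg$lead1
    streams$ecg_lead2 <- ecg$lead2
  }
  fot <- NULL
  if (with_fot) {
    fot <- lapply(c(low = "low", high = "high"), function(b) {
      lapply(seq_along(true_params), function(k) {
        generate_fot_signals(true_params[[k]],
          band = b, noise_sd = fot_noise_sd, breathing_frac = breathing_frac,
          seed = derive_seed(profile$seed, 100L + 2L * k + (b == "high"))
        )
      })
    })
  }
  structure(
    list(
      profile = profile, timeline = timeline, streams = streams,
      true_params = true_params, true_eta = true_eta,
      hr_session_means = hr_means, fot = fot
    ),
    class = "synthetic_session"
  )
}

#' @export
print.synthetic_session <- function(x, ...) {
  cat(sprintf(
    "<synthetic_session '%s'> %d sessions, %d streams%s, eta range [%.3g, %.3g]\n",
    x$profile$subject_id, x$timeline$n_sessions, length(x$streams),
    if (is.null(x$fot)) "" else ", FOT both bands",
    min(x$true_eta), max(x$true_eta)
  ))
  invisible(x)
}

#' Write a synthetic session to disk
#'
#' Streams go to one CSV per channel (`t_s`, `value`); each FOT record goes
#' to `fot_<band>_s<k>.csv` (`t_s`, `pressure`, `flow`) with a JSON sidecar
#' holding the excitation grid, band, seed and true parameters; the timeline
#' and profile are stored as JSON.
#'
#' @param session A [synthetic_session()].
#' @param dir Output directory (created if missing).
#' @return `dir` invisibly.
#' @export
write_session <- function(session, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  for (nm in names(session$streams)) {
    write_stream_csv(session$streams[[nm]], file.path(dir, paste0(nm, ".csv")))
  }
  write_timeline_json(session$timeline, file.path(dir, "timeline.json"))
  jsonlite::write_json(
    unclass(session$profile), file.path(dir, "profile.json"),
    auto_unbox = TRUE, digits = NA
  )
  jsonlite::write_json(
    lapply(session$true_params, function(p) {
      p[c("R", "L", "D", "alpha", "G", "H", "eta")]
    }),
    file.path(dir, "true_params.json"),
    auto_unbox = TRUE, digits = NA
  )
  if (!is.null(session$fot)) {
    for (b in names(session$fot)) {
      for (k in seq_along(session$fot[[b]])) {
        write_fot_csv(
          session$fot[[b]][[k]],
          file.path(dir, sprintf("fot_%s_s%02d.csv", b, k))
        )
      }
    }
  }
  invisible(dir)
}

#' Read and write FOT records as CSV
#'
#' @param record An `fot_record` from [generate_fot_signals()].
#' @param path CSV path; a `<path>.json` sidecar holds grid/band/seed and
#'   the true generating parameters.
#' @return `write_fot_csv` returns `path` invisibly; `read_fot_csv` returns
#'   an `fot_record` (with `true_params` when present in the sidecar).
#' @export
write_fot_csv <- function(record, path) {
  stopifnot(inherits(record, "fot_record"))
  utils::write.csv(
    data.frame(t_s = record$t_s, pressure = record$pressure, flow = record$flow),
    path,
    row.names = FALSE, quote = FALSE, fileEncoding = "UTF-8"
  )
  tp <- record$true_params
  jsonlite::write_json(
    list(
      grid = record$grid, band = record$band, fs = record$fs,
      seed = record$seed,
      true_params = if (!is.null(tp)) tp[c("R", "L", "D", "alpha", "eta")]
    ),
    paste0(path, ".json"),
    auto_unbox = TRUE, digits = NA
  )
  invisible(path)
}

#' @rdname write_fot_csv
#' @export
read_fot_csv <- function(path) {
  df <- utils::read.csv(path, fileEncoding = "UTF-8")
  meta <- jsonlite::read_json(paste0(path, ".json"), simplifyVector = TRUE)
  tp <- NULL
  if (!is.null(meta$true_params)) {
    tp <- constant_phase_params(
      R = meta$true_params$R, L = meta$true_params$L,
      D = meta$true_params$D, alpha = meta$true_params$alpha
    )
  }
  structure(
    list(
      t_s = df$t_s, pressure = df$pressure, flow = df$flow,
      grid = meta$grid, band = meta$band, fs = meta$fs,
      seed = meta$seed, true_params = tp
    ),
    class = "fot_record"
  )
}
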