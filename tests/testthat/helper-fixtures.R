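# Lazily computed, cached fixtures shared across test files. The cohort run
# and the lead-predictor fits are the expensive ones; everything downstream
# reuses them instead of retraining.

.fixture_env <- new.env(parent = emptyenv())

fixture <- function(name, expr) {
  if (!exists(name, envir = .fixture_env, inherits = FALSE)) {
    assign(name, force(expr), envir = .fixture_env)
  }
  get(name, envir = .fixture_env, inherits = FALSE)
}

default_timeline <- function() fixture("timeline", build_timeline())

# One mid-cohort subject with a full session (ECG + FOT) for generator and
# forecaster tests.
demo_session <- function() {
  fixture("demo_session", {
    p <- sample_subject_profiles(1, seed = 7)[[1L]]
    synthetic_session(p, default_timeline())
  })
}

# 20-subject low-band cohort: the estimation- and forecast-path evaluation
# at study scale (the setting mirrored by the acceptance script).
cohort20 <- function() {
  fixture("cohort20", {
    run_pipeline(run_config(n_subjects = 20, seed = 1, bands = "low"))
  })
}

pool_cohort <- function(res, source_name) {
  key <- if (source_name == "model") "estimates" else "forecasts"
  do.call(rbind, lapply(res$subjects, function(s) {
    tab <- s$bands$low[[key]]
    keep <- tab$source == source_name
    data.frame(
      true = s$true_eta[tab$session_index[keep]],
      hat = tab$eta_hat[keep]
    )
  }))
}

# A 30-s two-lead ECG at 128 Hz used by the lead-prediction tests: noiseless
# identity-transform pair plus a default-morphing pair.
lead_fixture_streams <- function() {
  fixture("lead_streams", {
    p <- subject_profile("L", 30, 70, 175,
      hr_baseline = 70, eta_baseline = 1.2, seed = 21
    )
    hr <- generate_hr_profile(30, p)
    clean <- generate_ecg(hr, identity_lead_transform(),
      seed = 3, fs = 128, noise_sd = 0
    )
    morph <- generate_ecg(hr, lead_transform(), seed = 3, fs = 128)
    list(clean = clean, morph = morph)
  })
}

lead_fit_identity <- function() {
  fixture("lead_fit_identity", {
    s <- lead_fixture_streams()
    predict_lead2_from_lead1(s$clean$lead1, s$clean$lead1,
      lead_predict_config(seed = 2)
    )
  })
}

lead_fit_affine <- function() {
  fixture("lead_fit_affine", {
    s <- lead_fixture_streams()
    lead2 <- sensor_stream(s$clean$lead2$t_s, 2 * s$clean$lead1$value,
      fs = 128, channel = "ecg_lead2", units = "mV"
    )
    predict_lead2_from_lead1(s$clean$lead1, lead2, lead_predict_config(seed = 2))
  })
}

lead_fit_morph <- function() {
  fixture("lead_fit_morph", {
    s <- lead_fixture_streams()
    predict_lead2_from_lead1(s$morph$lead1, s$morph$lead2,
      lead_predict_config(seed = 2)
    )
  })
}

# One-subject, both-band pipeline run with shortened training, used for
# manifest/counting and determinism checks.
small_pipeline_config <- function() {
  run_config(
    n_subjects = 1, seed = 3,
    estimator = list(max_epochs = 30L),
    forecaster = list(max_epochs = 30L)
  )
}

small_pipeline_run <- function() {
  fixture("small_pipeline_run", run_pipeline(small_pipeline_config()))
}
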