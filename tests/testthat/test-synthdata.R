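test_that("subject profiles enforce their invariants", {
  p <- subject_profile("S1", 30, 70, 175, hr_baseline = 70, eta_baseline = 1.2, seed = 1)
  expect_equal(p$bmi, 70 / 1.75^2)
  expect_error(
    subject_profile("S1", 30, 70, 175, 70, 1.2, bmi = 30, seed = 1),
    "inconsistent"
  )
  expect_error(subject_profile("S1", 30, 70, 175, 30, 1.2, seed = 1), "40, 180")
  expect_error(subject_profile("S1", 30, 70, 175, 70, -1, seed = 1), "positive")
  cohort <- sample_subject_profiles(6, seed = 2)
  expect_length(cohort, 6L)
  expect_true(all(vapply(cohort, function(x) x$eta_baseline, numeric(1)) > 0))
})

test_that("HR generator is seeded, bounded and degenerates to the baseline", {
  p <- subject_profile("S1", 30, 70, 175, 72, 1.2, seed = 10)
  flat <- generate_hr_profile(600, p, drift_sd = 0, noise_sd = 0)
  expect_equal(flat$value, rep(72, 600))
  a <- generate_hr_profile(3600, p)
  b <- generate_hr_profile(3600, p)
  expect_identical(a$value, b$value)
  expect_true(all(a$value >= 40 & a$value <= 180))
  expect_error(generate_hr_profile(-5, p), "invalid-argument")
})

test_that("HR series SD matches a direct-simulation oracle of the process", {
  # oracle: independent re-implementation of baseline + rescaled smoothed
  # random walk + white noise, at 10x the replicate count
  oracle_sd <- function(n_rep, duration = 7500, drift_sd = 3, noise_sd = 1.5) {
    win <- 600L; pad <- win
    mean(vapply(seq_len(n_rep), function(r) {
      set.seed(5000 + r)
      walk <- cumsum(rnorm(duration + 2L * pad))
      sm <- as.numeric(stats::filter(walk, rep(1 / win, win), sides = 2))
      sm <- sm[(pad + 1L):(pad + duration)]
      drift <- (sm - mean(sm)) / sd(sm) * drift_sd
      sd(pmin(pmax(72 + drift + rnorm(duration, 0, noise_sd), 40), 180))
    }, numeric(1)))
  }
  pkg_sds <- vapply(1:200, function(s) {
    p <- subject_profile("S", 30, 70, 175, 72, 1.2, seed = s)
    sd(generate_hr_profile(7500, p)$value)
  }, numeric(1))
  expect_equal(mean(pkg_sds), oracle_sd(2000), tolerance = 0.02)
})

test_that("two-lead ECG degenerates correctly and encodes the heart rate", {
  p <- subject_profile("S1", 30, 70, 175, 60, 1.2, seed = 4)
  hr60 <- generate_hr_profile(60, p, drift_sd = 0, noise_sd = 0)
  ecg <- generate_ecg(hr60, identity_lead_transform(), seed = 2, fs = 128, noise_sd = 0)
  # identity transform, zero noise: the leads coincide
  expect_identical(ecg$lead1$value, ecg$lead2$value)
  # constant HR 60: all interior beat intervals are exactly 1 s
  expect_equal(diff(ecg$beat_times), rep(1, length(ecg$beat_times) - 1L))
  # peak-detection oracle on the waveform recovers the beat times
  pk <- pracma::findpeaks(ecg$lead1$value, minpeakheight = 0.5, minpeakdistance = 40)
  expect_equal(nrow(pk), length(ecg$beat_times) - 1L, tolerance = 2)
  expect_error(
    generate_ecg(sensor_stream(numeric(0), numeric(0), fs = 1), seed = 1),
    "invalid-argument"
  )
})

test_that("ECG-rate recovery by peak detection stays within 2 beats/min", {
  p <- subject_profile("S1", 30, 70, 175, 75, 1.2, seed = 6)
  hr <- generate_hr_profile(120, p)
  ecg <- generate_ecg(hr, seed = 3, fs = 128)
  pk <- pracma::findpeaks(ecg$lead1$value,
    minpeakheight = 0.6, minpeakdistance = floor(128 * 60 / 180)
  )
  bt <- sort(ecg$lead1$t_s[pk[, 2]])
  hr_det <- 60 / diff(bt)
  t_mid <- (bt[-1] + bt[-length(bt)]) / 2
  hr_true <- approx(hr$t_s, hr$value, xout = t_mid, rule = 2)$y
  expect_lt(mean(abs(hr_det - hr_true)), 2)
})

test_that("session parameters realize the configured HR-eta coupling", {
  p0 <- subject_profile("S1", 30, 70, 175, 70, 1.4,
    coupling_gamma = 0, noise_sd_eta = 0, seed = 5
  )
  pars <- generate_session_params(p0, rep(c(65, 75), 5))
  expect_equal(vapply(pars, `[[`, numeric(1), "eta"), rep(1.4, 10))

  p1 <- subject_profile("S1", 30, 70, 175, 70, 1.4,
    coupling_gamma = 0.5, noise_sd_eta = 0, seed = 5
  )
  hrs <- seq(60, 80, length.out = 10)
  etas <- vapply(generate_session_params(p1, hrs), `[[`, numeric(1), "eta")
  expect_equal(etas, 1.4 * (1 + 0.5 * (hrs - 70) / 70), tolerance = 1e-12)
  expect_equal(cor(hrs, etas), 1)
  # alpha is back-computed from eta
  alphas <- vapply(generate_session_params(p1, hrs), `[[`, numeric(1), "alpha")
  expect_equal(1 / tan(alphas * pi / 2), etas, tolerance = 1e-12)
  expect_error(generate_session_params(p1, numeric(0), 0), "invalid-argument")
})

test_that("default coupling reproduces the moderate HR-eta correlation", {
  # 500 subjects x 10 sessions; mean sample correlation should sit near the
  # design target 0.4 and near the closed-form prediction
  # gamma*sd_hr / sqrt(gamma^2 sd_hr^2 + sd_eps^2 hr0^2 / eta0^2)
  tl <- build_timeline()
  win <- eqv_extraction_windows(tl)
  res <- vapply(1:500, function(s) {
    p <- subject_profile("S", 30, 70, 175, 72, 1.3, seed = s)
    hr <- generate_hr_profile(tl$total_duration * 60, p)
    m <- vapply(
      align_stream(hr, win),
      function(x) mean(x$value), numeric(1)
    )
    etas <- vapply(generate_session_params(p, m), `[[`, numeric(1), "eta")
    c(cor(m, etas), sd(m))
  }, numeric(2))
  mean_corr <- mean(res[1, ])
  sd_hr <- mean(res[2, ])
  closed_form <- 1 * sd_hr / sqrt(sd_hr^2 + 0.12^2 * 72^2 / 1.3^2)
  expect_lt(abs(mean_corr - 0.4), 0.1)
  expect_lt(abs(mean_corr - closed_form), 0.12)
})

test_that("multisine pressure has energy only on the excitation grid", {
  p <- constant_phase_params(R = 3, L = 0.01, D = 5, alpha = 0.6)
  rec <- generate_fot_signals(p, "low", noise_sd = 0, breathing_frac = 0, seed = 2)
  n <- length(rec$pressure)
  amp <- Mod(stats::fft(rec$pressure))[1:(n / 2)]
  bins <- round(rec$grid * n / rec$fs) + 1L
  on_grid <- sum(amp[bins]^2)
  total <- sum(amp^2)
  expect_lt((total - on_grid) / total, 1e-10)
})

test_that("the resistive limit gives flow = pressure / R pointwise", {
  p <- constant_phase_params(R = 2, L = 0, D = 1e-6, alpha = 0.5)
  rec <- generate_fot_signals(p, "high", noise_sd = 0, breathing_frac = 0, seed = 2)
  skip <- floor(0.1 * length(rec$t_s))
  keep <- (skip + 1):length(rec$t_s)
  expect_equal(rec$flow[keep], rec$pressure[keep] / 2, tolerance = 1e-5)
  expect_error(generate_fot_signals(p, "mid"), "arg")
})

test_that("synthetic sessions are reproducible and span the protocol", {
  ses <- demo_session()
  ses2 <- synthetic_session(ses$profile, ses$timeline)
  expect_identical(ses$streams$hr$value, ses2$streams$hr$value)
  expect_identical(ses$streams$ecg_lead2$value, ses2$streams$ecg_lead2$value)
  expect_identical(ses$true_eta, ses2$true_eta)
  dur <- ses$timeline$total_duration * 60
  for (nm in names(ses$streams)) {
    s <- ses$streams[[nm]]
    expect_gte(max(s$t_s) + 1 / attr(s, "fs"), dur)
  }
  # one true parameter set per session, eta positive
  expect_length(ses$true_params, 10L)
  expect_true(all(ses$true_eta > 0))
})

test_that("stream and FOT records survive CSV round trips", {
  ses <- demo_session()
  d <- tempfile()
  dir.create(d)
  write_stream_csv(ses$streams$hr, file.path(d, "hr.csv"))
  hr2 <- read_stream_csv(file.path(d, "hr.csv"), fs = 1, channel = "hr")
  expect_equal(hr2$value, ses$streams$hr$value, tolerance = 1e-12)
  rec <- ses$fot$low[[1]]
  write_fot_csv(rec, file.path(d, "fot.csv"))
  rec2 <- read_fot_csv(file.path(d, "fot.csv"))
  expect_equal(rec2$flow, rec$flow, tolerance = 1e-12)
  expect_equal(rec2$grid, rec$grid)
  expect_equal(rec2$true_params$eta, rec$true_params$eta, tolerance = 1e-12)
})
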