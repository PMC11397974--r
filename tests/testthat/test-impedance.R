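test_that("derived tissue parameters obey the constant-phase identities", {
  p <- constant_phase_params(R = 2, L = 0.01, D = 5, alpha = 0.5)
  expect_equal(p$eta, 1) # G = H at alpha = 0.5
  expect_equal(p$G^2 + p$H^2, p$D^2, tolerance = 1e-12)
  # closed-form oracle: cot(0.3*pi) evaluated independently
  p6 <- constant_phase_params(R = 1, L = 0, D = 1, alpha = 0.6)
  expect_equal(compute_eta(p6), cos(0.3 * pi) / sin(0.3 * pi), tolerance = 1e-12)
  expect_equal(compute_eta(p6), 0.7265425, tolerance = 1e-6)
  expect_error(compute_eta(list(G = 0, H = 0)), "invalid-argument")
  expect_error(constant_phase_params(1, 0.01, 5, 1.2), "invalid-argument")
  expect_error(constant_phase_params(1, 0.01, -1, 0.5), "invalid-argument")
})

test_that("eta is strictly decreasing in alpha", {
  alphas <- seq(0.005, 0.995, length.out = 100)
  etas <- vapply(
    alphas,
    function(a) constant_phase_params(1, 0, 1, a)$eta, numeric(1)
  )
  expect_true(all(diff(etas) < 0))
})

test_that("parameterization consistency holds for fitted results", {
  set.seed(5)
  p <- constant_phase_params(R = 3, L = 0.012, D = 6, alpha = 0.62)
  f <- band_grid("low")
  z <- constant_phase_impedance(f, p)
  fit <- fit_constant_phase(impedance_spectrum(f, z, band = "low"))
  expect_lt(abs(fit$G - fit$D * cos(fit$alpha * pi / 2)), 1e-9 * fit$D)
  expect_lt(abs(fit$H - fit$D * sin(fit$alpha * pi / 2)), 1e-9 * fit$D)
})

test_that("spectrum estimation recovers a pure resistance exactly", {
  R <- 2.5
  fs <- 100
  tt <- (0:11999) / fs
  grid <- band_grid("low")
  pressure <- rowSums(sapply(grid, function(f) cos(2 * pi * f * tt + f)))
  flow <- pressure / R
  sp <- estimate_spectrum(pressure, flow, grid, fs, band = "low")
  expect_equal(Re(sp$z_values), rep(R, length(grid)), tolerance = 1e-10)
  expect_equal(Im(sp$z_values), rep(0, length(grid)), tolerance = 1e-10)
})

test_that("noiseless generator round trip reproduces Z and the parameters", {
  p <- constant_phase_params(R = 3, L = 0.01, D = 5, alpha = 0.7)
  for (b in c("low", "high")) {
    rec <- generate_fot_signals(p, band = b, noise_sd = 0, breathing_frac = 0, seed = 3)
    sp <- estimate_spectrum(rec$pressure, rec$flow, rec$grid, rec$fs, band = b)
    z_true <- constant_phase_impedance(sp$frequencies, p)
    expect_lt(max(Mod(sp$z_values - z_true) / Mod(z_true)), 1e-6)
    fit <- fit_constant_phase(sp)
    expect_equal(fit$R, p$R, tolerance = 1e-6)
    expect_equal(fit$L, p$L, tolerance = 1e-6)
    expect_equal(fit$D, p$D, tolerance = 1e-6)
    expect_equal(fit$alpha, p$alpha, tolerance = 1e-6)
    expect_equal(fit$eta, p$eta, tolerance = 1e-6)
    expect_lt(fit$fit_residual, 1e-10)
  }
})

test_that("eta is band-independent for a common parameter set", {
  p <- constant_phase_params(R = 2.2, L = 0.008, D = 4, alpha = 0.55)
  etas <- vapply(c("low", "high"), function(b) {
    rec <- generate_fot_signals(p, band = b, noise_sd = 0, breathing_frac = 0, seed = 9)
    fit_constant_phase(
      estimate_spectrum(rec$pressure, rec$flow, rec$grid, rec$fs, band = b)
    )$eta
  }, numeric(1))
  expect_equal(unname(diff(etas)), 0, tolerance = 1e-6)
})

test_that("the NLS optimum matches an exhaustive (D, alpha) grid search", {
  # profile the residual over a 100 x 100 grid at the true (R, L); the NLS
  # solution must land within one grid cell of the exhaustive optimum
  set.seed(6)
  f <- band_grid("high")
  w <- 2 * pi * f
  for (inst in 1:10) {
    p <- constant_phase_params(
      R = runif(1, 1, 4), L = runif(1, 0.003, 0.02),
      D = runif(1, 2, 8), alpha = runif(1, 0.3, 0.8)
    )
    z <- constant_phase_impedance(f, p)
    z <- z + complex(
      real = rnorm(length(f), 0, 0.005 * Mod(z)),
      imaginary = rnorm(length(f), 0, 0.005 * Mod(z))
    )
    fit <- fit_constant_phase(impedance_spectrum(f, z, band = "high"))
    # profile the residual over (D, alpha) holding (R, L) at the fitted
    # optimum: the exhaustive minimum must coincide with the NLS solution
    d_grid <- seq(0.5 * p$D, 1.5 * p$D, length.out = 100)
    a_grid <- seq(0.05, 0.95, length.out = 100)
    rss <- outer(d_grid, a_grid, Vectorize(function(d, a) {
      zm <- fit$R + 1i * w * fit$L +
        d * (cos(a * pi / 2) - 1i * sin(a * pi / 2)) * w^(-a)
      sum(Mod(zm - z)^2)
    }))
    best <- arrayInd(which.min(rss), dim(rss))
    # no grid node beats the NLS solution, and the grid optimum sits in the
    # same neighbourhood (the (D, alpha) valley is correlated, so D can be a
    # couple of cells off when alpha snaps to its nearest grid line)
    expect_lte(fit$fit_residual, min(rss) + 1e-10)
    expect_lt(abs(fit$alpha - a_grid[best[2]]), diff(a_grid[1:2]) * 1.5)
    expect_lt(abs(fit$D - d_grid[best[1]]), diff(d_grid[1:2]) * 3)
  }
})

test_that("eta survives 1 percent complex noise with small median error", {
  set.seed(8)
  p <- constant_phase_params(R = 3, L = 0.01, D = 5, alpha = 0.65)
  f <- band_grid("low")
  z0 <- constant_phase_impedance(f, p)
  errs <- replicate(500, {
    z <- z0 + complex(
      real = rnorm(8, 0, 0.01 * Mod(z0)),
      imaginary = rnorm(8, 0, 0.01 * Mod(z0))
    )
    fit <- fit_constant_phase(impedance_spectrum(f, z, band = "low"))
    abs(fit$eta - p$eta) / p$eta
  })
  expect_lt(median(errs), 0.05)
})

test_that("spectrum inputs are validated", {
  expect_error(
    estimate_spectrum(numeric(0), numeric(0), band_grid("low"), 100, "low"),
    "invalid-argument"
  )
  expect_error(
    estimate_spectrum(rnorm(100), rnorm(99), band_grid("low"), 100, "low"),
    "invalid-argument"
  )
  # flow with no energy at a grid bin
  fs <- 100
  tt <- (0:11999) / fs
  pressure <- cos(2 * pi * 0.2 * tt)
  expect_error(
    estimate_spectrum(pressure, rep(0, length(tt)), band_grid("low"), fs, "low"),
    "degenerate-input"
  )
  expect_error(
    impedance_spectrum(c(0.2, 0.4, 0.6), complex(3, 1, 1), band = "low"),
    "at least 4"
  )
  expect_error(
    impedance_spectrum(c(3, 4, 5, 6), complex(4, 1, 1), band = "low"),
    "outside the declared band"
  )
})

test_that("spectrum and parameter files round-trip through CSV/JSON", {
  p <- constant_phase_params(R = 3, L = 0.01, D = 5, alpha = 0.7)
  f <- band_grid("high")
  sp <- impedance_spectrum(f, constant_phase_impedance(f, p),
    band = "high", session_index = 4L
  )
  path <- tempfile(fileext = ".csv")
  write_spectrum_csv(sp, path)
  sp2 <- read_spectrum_csv(path)
  expect_equal(sp2$frequencies, sp$frequencies)
  expect_equal(sp2$z_values, sp$z_values, tolerance = 1e-12)
  expect_equal(sp2$band, "high")
  expect_equal(sp2$session_index, 4L)
})
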