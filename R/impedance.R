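#' Constant-phase respiratory impedance model
#'
#' The respiratory input impedance is modelled as
#' \deqn{Z(j\omega) = R + j\omega L + (G - jH)\,\omega^{-\alpha},}
#' with airway resistance `R` (cmH2O.s/L), inertance `L` (cmH2O.s^2/L), and a
#' tissue term of magnitude `D` and phase set by the exponent
#' `alpha` in (0, 1): tissue damping \eqn{G = D\cos(\alpha\pi/2)} and tissue
#' elastance \eqn{H = D\sin(\alpha\pi/2)}. The tissue hysteresivity is
#' \eqn{\eta = G/H = \cot(\alpha\pi/2)}, the damping/elastance ratio that
#' indexes tissue heterogeneity and remodelling.
#'
#' @param R Airway resistance, `>= 0`.
#' @param L Inertance, `>= 0`.
#' @param D Tissue coefficient magnitude, `> 0`.
#' @param alpha Constant-phase exponent in (0, 1).
#' @param fit_residual Optional sum of squared complex residuals from a fit.
#' @param diagnostics Optional list of fit diagnostics.
#' @return A list of class `constant_phase_params` with fields `R`, `L`, `D`,
#'   `alpha`, derived `G`, `H`, `eta`, and `fit_residual`.
#' @examples
#' p <- constant_phase_params(R = 2, L = 0.01, D = 5, alpha = 0.5)
#' p$eta # 1: damping equals elastance at alpha = 0.5
#' @export
constant_phase_params <- function(R, L, D, alpha, fit_residual = NA_real_,
                                  diagnostics = NULL) {
  if (R < 0 || L < 0) stop("invalid-argument: R and L must be non-negative")
  if (D <= 0) stop("invalid-argument: D must be positive")
  if (alpha <= 0 || alpha >= 1) stop("invalid-argument: alpha must lie in (0, 1)")
  phi <- alpha * pi / 2
  G <- D * cos(phi)
  H <- D * sin(phi)
  structure(
    list(
      R = R, L = L, D = D, alpha = alpha,
      G = G, H = H, eta = G / H,
      fit_residual = fit_residual, diagnostics = diagnostics
    ),
    class = "constant_phase_params"
  )
}

#' @export
print.constant_phase_params <- function(x, ...) {
  cat(sprintf(
    "<constant_phase_params> R = %.4g, L = %.4g, D = %.4g, alpha = %.4g | G = %.4g, H = %.4g, eta = %.4g\n",
    x$R, x$L, x$D, x$alpha, x$G, x$H, x$eta
  ))
  invisible(x)
}

#' Evaluate the constant-phase model at given frequencies
#'
#' @param f Frequencies in Hz (`omega = 2*pi*f`).
#' @param params A [constant_phase_params()].
#' @return Complex impedance values, cmH2O.s/L.
#' @export
constant_phase_impedance <- function(f, params) {
  w <- 2 * pi * f
  params$R + 1i * w * params$L + (params$G - 1i * params$H) * w^(-params$alpha)
}

#' Tissue hysteresivity from fitted parameters
#'
#' Returns `G/H`, which under the D-parameterization equals
#' `cot(alpha*pi/2)`.
#'
#' @param params A [constant_phase_params()] (or any list with `G`, `H`).
#' @return The dimensionless hysteresivity coefficient.
#' @export
compute_eta <- function(params) {
  if (is.null(params$H) || !is.finite(params$H) || params$H <= 0) {
    stop("invalid-argument: tissue elastance H must be positive")
  }
  params$G / params$H
}

# eta = cot(alpha*pi/2) and its inverse; used by the session generator to
# back-compute alpha from a target hysteresivity.
eta_from_alpha <- function(alpha) 1 / tan(alpha * pi / 2)

alpha_from_eta <- function(eta) {
  if (any(eta <= 0)) stop("invalid-argument: eta must be positive")
  (2 / pi) * atan(1 / eta)
}

#' Default excitation grids for the two measurement bands
#'
#' The low band (0.2–2 Hz, 4P-FOT prototype) probes tissue viscoelasticity
#' near the breathing frequency; the high band (5–37 Hz, RESMON) probes
#' airway resistance and reactance.
#'
#' @param band `"low"` or `"high"`.
#' @return Numeric vector of excitation frequencies in Hz.
#' @export
band_grid <- function(band = c("low", "high")) {
  band <- match.arg(band)
  switch(band,
    low = c(0.2, 0.4, 0.6, 0.8, 1.0, 1.2, 1.6, 2.0),
    high = c(5, 11, 17, 23, 29, 37)
  )
}

band_range <- function(band) {
  switch(band, low = c(0.2, 2), high = c(5, 37),
    stop("invalid-argument: unknown band '", band, "'")
  )
}

#' Impedance spectrum container
#'
#' @param frequencies Strictly increasing frequencies in Hz, at least 4 (the
#'   constant-phase model has four free parameters).
#' @param z_values Complex impedance at those frequencies.
#' @param band `"low"` or `"high"`; frequencies must lie within the band.
#' @param session_index 1-based measurement session number.
#' @return A list of class `impedance_spectrum`.
#' @export
impedance_spectrum <- function(frequencies, z_values, band = c("low", "high"),
                               session_index = 1L) {
  band <- match.arg(band)
  if (length(frequencies) != length(z_values)) {
    stop("invalid-argument: frequency and impedance vectors differ in length")
  }
  if (length(frequencies) < 4L) {
    stop("invalid-argument: need at least 4 frequencies to identify 4 parameters")
  }
  if (any(diff(frequencies) <= 0)) {
    stop("invalid-argument: frequencies must be strictly increasing")
  }
  if (anyNA(frequencies) || anyNA(z_values) || any(!is.finite(abs(z_values)))) {
    stop("invalid-argument: NaN/Inf entries in spectrum")
  }
  rng <- band_range(band)
  if (min(frequencies) < rng[1] - 1e-9 || max(frequencies) > rng[2] + 1e-9) {
    stop("invalid-argument: frequencies outside the declared band range")
  }
  structure(
    list(
      frequencies = as.numeric(frequencies),
      z_values = as.complex(z_values),
      band = band, session_index = as.integer(session_index)
    ),
    class = "impedance_spectrum"
  )
}

#' @export
print.impedance_spectrum <- function(x, ...) {
  cat(sprintf(
    "<impedance_spectrum> band '%s', session %d, %d frequencies [%g, %g] Hz\n",
    x$band, x$session_index, length(x$frequencies),
    min(x$frequencies), max(x$frequencies)
  ))
  invisible(x)
}

# Approximate rational gcd of the grid frequencies; 1/gcd is the shortest
# record length containing an integer number of periods of every component.
grid_base_period <- function(grid) {
  ints <- round(grid * 1e6)
  g <- ints[1]
  for (v in ints[-1]) {
    a <- g; b <- v
    while (b != 0) { t <- b; b <- a %% b; a <- t }
    g <- a
  }
  1e6 / g
}

#' Estimate the impedance spectrum from pressure and flow records
#'
#' Computes \eqn{Z(f) = P(f)/Q(f)} from discrete Fourier coefficients of the
#' pressure and flow signals at each excitation-grid frequency. The leading
#' 10\% of the record is discarded as transient, the mean is removed, and the
#' record is trimmed to an integer number of periods of every grid frequency
#' so the grid components fall exactly on Fourier bins.
#'
#' Tidal breathing contributes a large flow component near 0.2--0.3 Hz that
#' in general does not span an integer number of periods of the trimmed
#' record and therefore leaks into the excitation bins — a serious bias for
#' the low band, whose grid brackets the breathing frequency. With
#' `breathing_reject = TRUE` (the default) the estimator locates the
#' dominant off-grid component in the 0.08--0.5 Hz band by least squares and
#' regresses it out of both channels before evaluating the grid
#' coefficients; when no such component is present the fitted amplitude is
#' ~0 and the correction is a no-op.
#'
#' @param pressure,flow Equal-length numeric vectors (or [sensor_stream()]s)
#'   sampled at `fs`.
#' @param grid Excitation frequencies in Hz.
#' @param fs Sampling rate in Hz; must exceed `2 * max(grid)`.
#' @param band,session_index Metadata for the returned spectrum.
#' @param breathing_reject Remove the dominant sub-grid breathing component
#'   before estimating the grid coefficients (default `TRUE`).
#' @return An [impedance_spectrum()].
#' @export
estimate_spectrum <- function(pressure, flow, grid, fs,
                              band = c("low", "high"), session_index = 1L,
                              breathing_reject = TRUE) {
  band <- match.arg(band)
  if (is_sensor_stream(pressure)) pressure <- pressure$value
  if (is_sensor_stream(flow)) flow <- flow$value
  if (length(pressure) == 0L || length(flow) == 0L) {
    stop("invalid-argument: empty pressure or flow record")
  }
  if (length(pressure) != length(flow)) {
    stop("invalid-argument: pressure and flow records differ in length")
  }
  if (fs <= 2 * max(grid)) {
    stop("invalid-argument: fs must exceed twice the highest grid frequency")
  }
  n0 <- length(pressure)
  skip <- floor(0.10 * n0)
  p <- pressure[(skip + 1L):n0]
  q <- flow[(skip + 1L):n0]
  # trim to an integer number of periods of every grid frequency
  t0 <- grid_base_period(grid)
  n_per <- round(t0 * fs)
  if (abs(t0 * fs - n_per) > 1e-6) {
    stop("invalid-argument: grid base period is not an integer number of samples at fs")
  }
  n_use <- (length(p) %/% n_per) * n_per
  if (n_use < n_per) {
    stop("invalid-argument: record too short to resolve the grid frequencies")
  }
  p <- p[seq_len(n_use)] - mean(p[seq_len(n_use)])
  q <- q[seq_len(n_use)] - mean(q[seq_len(n_use)])
  tt <- (seq_len(n_use) - 1) / fs
  if (breathing_reject) {
    grid_basis <- do.call(cbind, lapply(grid, function(f) {
      cbind(sin(2 * pi * f * tt), cos(2 * pi * f * tt))
    }))
    # scan for breathing on the excitation-free residual, so leakage of the
    # excitation itself can never masquerade as a breathing component
    q_perp <- stats::lsfit(grid_basis, q, intercept = FALSE)$residuals
    fb <- find_breathing_freq(q_perp, mean(q^2), tt, grid, n_use / fs)
    if (!is.na(fb)) {
      # estimate the breathing coefficients jointly with the grid basis and
      # subtract only the breathing part, leaving grid energy untouched
      breath <- cbind(sin(2 * pi * fb * tt), cos(2 * pi * fb * tt))
      joint <- cbind(breath, grid_basis)
      for (ch in c("q", "p")) {
        x <- get(ch)
        coefs <- stats::lsfit(joint, x, intercept = FALSE)$coefficients
        assign(ch, x - breath %*% coefs[1:2])
      }
    }
  }
  z <- vapply(grid, function(f) {
    e <- exp(-2i * pi * f * tt)
    pc <- sum(p * e)
    qc <- sum(q * e)
    if (Mod(qc) / n_use < 1e-12) {
      stop(sprintf("degenerate-input: no flow energy at grid frequency %g Hz", f))
    }
    pc / qc
  }, complex(1))
  impedance_spectrum(grid, z, band = band, session_index = session_index)
}

# Locate the dominant component in the tidal-breathing band (0.08-0.5 Hz)
# of the excitation-free flow residual by scanning a fine frequency grid for
# the largest least-squares sinusoid amplitude; candidates closer than 1.5
# resolution bins to an excitation line are excluded. Returns NA when
# nothing in the band carries at least 0.1% of the total flow power.
find_breathing_freq <- function(q_perp, q_power, tt, grid, t_rec) {
  df <- 1 / (4 * t_rec)
  cand <- seq(0.08, 0.5, by = df)
  cand <- cand[vapply(
    cand,
    function(f) all(abs(f - grid) > 1.5 / t_rec), logical(1)
  )]
  if (!length(cand)) return(NA_real_)
  amp2 <- vapply(cand, function(f) {
    s <- sin(2 * pi * f * tt); cc <- cos(2 * pi * f * tt)
    fit <- stats::lsfit(cbind(s, cc), q_perp, intercept = FALSE)
    sum(fit$coefficients^2)
  }, numeric(1))
  best <- which.max(amp2)
  if (amp2[best] / 2 < 1e-3 * q_power) return(NA_real_)
  cand[best]
}

# For a fixed alpha the model is linear in (R, L, D): profile linear least
# squares used for initialization and by the exhaustive-search oracle.
profile_fit_alpha <- function(spectrum, alpha) {
  w <- 2 * pi * spectrum$frequencies
  phi <- alpha * pi / 2
  # columns of the complex design matrix for (R, L, D)
  basis <- cbind(
    rep(1 + 0i, length(w)),
    1i * w,
    (cos(phi) - 1i * sin(phi)) * w^(-alpha)
  )
  A <- rbind(Re(basis), Im(basis))
  y <- c(Re(spectrum$z_values), Im(spectrum$z_values))
  coef <- tryCatch(qr.solve(A, y), error = function(e) c(NA, NA, NA))
  if (anyNA(coef)) return(NULL)
  coef <- pmax(coef, c(0, 0, 1e-6))
  rss <- sum((A %*% coef - y)^2)
  list(R = coef[1], L = coef[2], D = coef[3], alpha = alpha, rss = rss)
}

#' Identify constant-phase parameters from an impedance spectrum
#'
#' Minimizes the sum of squared complex residuals
#' \eqn{\sum_f |Z_{obs}(f) - Z(j2\pi f; R, L, D, \alpha)|^2} by multistart
#' Levenberg–Marquardt nonlinear least squares. Starting points combine a
#' linear pre-fit of `R` and `L`, eight log-spaced `D` values, `alpha` starts
#' \{0.3, 0.5, 0.7\}, and a profiled linear fit over an `alpha` grid (the
#' model is linear in `(R, L, D)` at fixed `alpha`). Bounds: `R, L >= 0`,
#' `D` in `[1e-6, 1e6]`, `alpha` in `[0.01, 0.99]`.
#'
#' @param spectrum An [impedance_spectrum()].
#' @return A [constant_phase_params()] with `fit_residual` and convergence
#'   diagnostics.
#' @export
fit_constant_phase <- function(spectrum) {
  stopifnot(inherits(spectrum, "impedance_spectrum"))
  f <- spectrum$frequencies
  zobs <- spectrum$z_values
  if (length(f) < 4L) stop("invalid-argument: fewer than 4 frequencies")
  w <- 2 * pi * f

  resid_fn <- function(p) {
    zm <- p[1] + 1i * w * p[2] +
      p[3] * (cos(p[4] * pi / 2) - 1i * sin(p[4] * pi / 2)) * w^(-p[4])
    c(Re(zm - zobs), Im(zm - zobs))
  }

  # linear pre-fit: R from the high-frequency real part, L from the
  # high-frequency reactance slope
  n <- length(f)
  r0 <- max(min(Re(zobs)), 1e-3)
  l0 <- max((Im(zobs)[n] - Im(zobs)[n - 1]) / (w[n] - w[n - 1]), 0)
  starts <- list()
  for (d0 in 10^seq(-2, 3, length.out = 8)) {
    for (a0 in c(0.3, 0.5, 0.7)) {
      starts[[length(starts) + 1L]] <- c(r0, l0, d0, a0)
    }
  }
  prof <- lapply(seq(0.05, 0.95, by = 0.05), function(a) profile_fit_alpha(spectrum, a))
  prof <- Filter(Negate(is.null), prof)
  if (length(prof)) {
    best_prof <- prof[[which.min(vapply(prof, `[[`, numeric(1), "rss"))]]
    starts[[length(starts) + 1L]] <-
      c(best_prof$R, best_prof$L, best_prof$D, best_prof$alpha)
  }

  lower <- c(0, 0, 1e-6, 0.01)
  upper <- c(Inf, Inf, 1e6, 0.99)
  best <- NULL
  n_conv <- 0L
  for (p0 in starts) {
    fit <- tryCatch(
      minpack.lm::nls.lm(
        par = pmin(pmax(p0, lower), upper), lower = lower, upper = upper,
        fn = resid_fn,
        control = minpack.lm::nls.lm.control(
          ftol = 1e-12, ptol = 1e-12, maxiter = 500
        )
      ),
      error = function(e) NULL
    )
    if (is.null(fit) || fit$info %in% c(0L, 5L, 9L)) next
    n_conv <- n_conv + 1L
    rss <- sum(fit$fvec^2)
    if (is.null(best) || rss < best$rss) best <- list(par = fit$par, rss = rss, info = fit$info)
  }
  if (is.null(best)) {
    stop(sprintf(
      "fit-failure: none of %d starts converged (band '%s', session %d)",
      length(starts), spectrum$band, spectrum$session_index
    ))
  }
  constant_phase_params(
    R = best$par[1], L = best$par[2], D = best$par[3], alpha = best$par[4],
    fit_residual = best$rss,
    diagnostics = list(
      n_starts = length(starts), n_converged = n_conv, info = best$info,
      band = spectrum$band, session_index = spectrum$session_index
    )
  )
}

#' Read and write impedance spectra as CSV
#'
#' Spectrum CSV has columns `freq_hz`, `z_real`, `z_imag`; band and session
#' metadata travel in a JSON sidecar (`<path>.json`).
#'
#' @param spectrum An [impedance_spectrum()].
#' @param path CSV file path.
#' @return `write_spectrum_csv` returns `path` invisibly; `read_spectrum_csv`
#'   returns an [impedance_spectrum()].
#' @export
write_spectrum_csv <- function(spectrum, path) {
  stopifnot(inherits(spectrum, "impedance_spectrum"))
  utils::write.csv(
    data.frame(
      freq_hz = spectrum$frequencies,
      z_real = Re(spectrum$z_values),
      z_imag = Im(spectrum$z_values)
    ),
    path,
    row.names = FALSE, quote = FALSE, fileEncoding = "UTF-8"
  )
  jsonlite::write_json(
    list(band = spectrum$band, session_index = spectrum$session_index),
    paste0(path, ".json"),
    auto_unbox = TRUE
  )
  invisible(path)
}

#' @rdname write_spectrum_csv
#' @export
read_spectrum_csv <- function(path) {
  df <- utils::read.csv(path, fileEncoding = "UTF-8")
  meta <- jsonlite::read_json(paste0(path, ".json"), simplifyVector = TRUE)
  impedance_spectrum(df$freq_hz, complex(real = df$z_real, imaginary = df$z_imag),
    band = meta$band, session_index = meta$session_index
  )
}

#' Export fitted parameters as a JSON report
#'
#' @param params A [constant_phase_params()].
#' @param path JSON file path.
#' @return `path` invisibly.
#' @export
write_params_json <- function(params, path) {
  stopifnot(inherits(params, "constant_phase_params"))
  jsonlite::write_json(
    params[c("R", "L", "D", "alpha", "G", "H", "eta", "fit_residual", "diagnostics")],
    path,
    auto_unbox = TRUE, digits = NA
  )
  invisible(path)
}
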