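#' Preprocessing configuration
#'
#' Parameters for the stream-cleaning steps applied before model input:
#' Hampel (sliding-median) outlier replacement, optional moving-average
#' smoothing and z-score normalization.
#'
#' @param hampel_window Odd window length in samples for the Hampel filter
#'   (default 11).
#' @param hampel_nsigma Rejection threshold in robust standard deviations
#'   (default 3).
#' @param smooth_window Moving-average window in samples (default 5).
#' @param normalization `"zscore"` or `"none"`.
#' @return A list of class `preprocess_config`.
#' @export
preprocess_config <- function(hampel_window = 11L, hampel_nsigma = 3,
                              smooth_window = 5L,
                              normalization = c("zscore", "none")) {
  normalization <- match.arg(normalization)
  if (hampel_window < 3 || hampel_window %% 2 == 0) {
    stop("invalid-argument: 'hampel_window' must be odd and >= 3")
  }
  if (hampel_nsigma <= 0) stop("invalid-argument: 'hampel_nsigma' must be positive")
  if (smooth_window < 1) stop("invalid-argument: 'smooth_window' must be >= 1")
  structure(
    list(
      hampel_window = as.integer(hampel_window), hampel_nsigma = hampel_nsigma,
      smooth_window = as.integer(smooth_window), normalization = normalization
    ),
    class = "preprocess_config"
  )
}

#' Replace outliers by the sliding-window median (Hampel rule)
#'
#' A sample deviating from the median of its centered window by more than
#' `nsigma * 1.4826 * MAD` (MAD taken over the same window) is replaced by
#' that window median; all other samples and all timestamps are unchanged.
#' Windows shrink at the series edges. A constant window has zero MAD and
#' triggers no replacement.
#'
#' @param series A [sensor_stream()].
#' @param cfg A [preprocess_config()].
#' @return A [sensor_stream()] of the same length.
#' @export
remove_outliers <- function(series, cfg = preprocess_config()) {
  stopifnot(is_sensor_stream(series))
  n <- nrow(series)
  if (n == 0L) stop("invalid-argument: empty series")
  k <- (cfg$hampel_window - 1L) %/% 2L
  if (n < cfg$hampel_window) {
    warning("series shorter than Hampel window; returned unchanged")
    return(series)
  }
  x <- series$value
  out <- x
  for (i in seq_len(n)) {
    lo <- max(1L, i - k)
    hi <- min(n, i + k)
    w <- x[lo:hi]
    med <- stats::median(w)
    sigma <- 1.4826 * stats::median(abs(w - med))
    if (sigma > 0 && abs(x[i] - med) > cfg$hampel_nsigma * sigma) {
      out[i] <- med
    }
  }
  stream_with_values(series, out)
}

#' Z-score normalization with stored inverse transform
#'
#' Standardizes a stream to mean 0 and (population) standard deviation 1 and
#' retains the transform parameters so model predictions can be mapped back
#' to physical units.
#'
#' @param series A [sensor_stream()] with non-zero variance.
#' @return The normalized [sensor_stream()], with attributes `norm_mean` and
#'   `norm_sd`.
#' @seealso [denormalize()]
#' @export
normalize <- function(series) {
  stopifnot(is_sensor_stream(series))
  x <- series$value
  if (length(x) == 0L) stop("invalid-argument: empty series")
  m <- mean(x)
  s <- sqrt(mean((x - m)^2)) # population SD
  if (s <= 0) stop("degenerate-input: zero variance, cannot normalize")
  out <- stream_with_values(series, (x - m) / s)
  attr(out, "norm_mean") <- m
  attr(out, "norm_sd") <- s
  out
}

#' @rdname normalize
#' @param series A normalized stream carrying `norm_mean`/`norm_sd`
#'   attributes.
#' @export
denormalize <- function(series) {
  stopifnot(is_sensor_stream(series))
  m <- attr(series, "norm_mean")
  s <- attr(series, "norm_sd")
  if (is.null(m) || is.null(s)) {
    stop("invalid-argument: stream carries no normalization parameters")
  }
  out <- stream_with_values(series, series$value * s + m)
  attr(out, "norm_mean") <- NULL
  attr(out, "norm_sd") <- NULL
  out
}

#' Centered moving-average smoothing
#'
#' Smooths a stream with a centered moving average; at the boundaries the
#' window shrinks symmetrically (edge truncation), so the output has the same
#' length and a window of 1 is the identity.
#'
#' @param series A [sensor_stream()].
#' @param window Window length in samples (odd windows are symmetric; an even
#'   window uses `window %/% 2` samples on each side).
#' @return A [sensor_stream()] of the same length.
#' @export
smooth_stream <- function(series, window = 5L) {
  stopifnot(is_sensor_stream(series))
  if (window < 1) stop("invalid-argument: 'window' must be >= 1")
  n <- nrow(series)
  if (n == 0L) stop("invalid-argument: empty series")
  k <- as.integer(window) %/% 2L
  if (k == 0L) return(series)
  x <- series$value
  cs <- cumsum(c(0, x))
  i <- seq_len(n)
  lo <- pmax(1L, i - k)
  hi <- pmin(n, i + k)
  stream_with_values(series, (cs[hi + 1L] - cs[lo]) / (hi - lo + 1L))
}

#' Standard heart-rate cleaning pipeline
#'
#' Applies Hampel outlier replacement followed by moving-average smoothing,
#' per the configured windows. Normalization is applied separately where a
#' model consumes the stream, so its parameters can be fitted on training
#' data only.
#'
#' @inheritParams remove_outliers
#' @return A cleaned [sensor_stream()].
#' @export
preprocess_stream <- function(series, cfg = preprocess_config()) {
  out <- remove_outliers(series, cfg)
  smooth_stream(out, cfg$smooth_window)
}
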