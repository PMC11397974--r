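#' Sensor stream container
#'
#' A `sensor_stream` holds one timestamped physiological channel (an ECG lead,
#' heart rate, respiratory rate, skin temperature, ...) sampled at a fixed
#' rate. Internally it is a data frame with columns `t_s` (seconds from the
#' protocol origin) and `value`, carrying the sampling rate, channel name and
#' units as attributes.
#'
#' @param t_s Numeric vector of timestamps in seconds, strictly increasing.
#' @param value Numeric vector of samples, same length as `t_s`.
#' @param fs Sampling rate in Hz.
#' @param channel Channel label, e.g. `"hr"`, `"ecg_lead1"`.
#' @param units Unit string, e.g. `"bpm"`, `"mV"`.
#' @return An object of class `sensor_stream`.
#' @examples
#' s <- sensor_stream(0:9, rnorm(10), fs = 1, channel = "hr", units = "bpm")
#' length(s$value)
#' @export
sensor_stream <- function(t_s, value, fs, channel = "signal", units = "") {
  if (length(t_s) != length(value)) {
    stop("invalid-argument: 't_s' and 'value' must have equal length")
  }
  if (length(t_s) > 1L && any(diff(t_s) <= 0)) {
    stop("invalid-argument: timestamps must be strictly increasing")
  }
  if (!is.numeric(fs) || length(fs) != 1L || fs <= 0) {
    stop("invalid-argument: 'fs' must be a positive scalar")
  }
  out <- data.frame(t_s = as.numeric(t_s), value = as.numeric(value))
  structure(out,
    fs = fs, channel = channel, units = units,
    class = c("sensor_stream", "data.frame")
  )
}

#' @export
print.sensor_stream <- function(x, ...) {
  cat(sprintf(
    "<sensor_stream '%s'> %d samples @ %g Hz, t = [%g, %g] s%s\n",
    attr(x, "channel"), nrow(x), attr(x, "fs"),
    if (nrow(x)) min(x$t_s) else NA, if (nrow(x)) max(x$t_s) else NA,
    if (nzchar(attr(x, "units"))) paste0(" [", attr(x, "units"), "]") else ""
  ))
  invisible(x)
}

#' @rdname sensor_stream
#' @param x Object to test or a `sensor_stream`.
#' @export
is_sensor_stream <- function(x) inherits(x, "sensor_stream")

# Rebuild a stream with new values but identical time base / metadata.
stream_with_values <- function(stream, value) {
  sensor_stream(stream$t_s, value,
    fs = attr(stream, "fs"),
    channel = attr(stream, "channel"), units = attr(stream, "units")
  )
}

#' Read and write sensor streams as CSV
#'
#' Streams are exchanged as plain CSV with columns `t_s` (seconds from the
#' session origin) and `value`, one file per channel, UTF-8 with a header row
#' and `.` as decimal separator.
#'
#' @param stream A [sensor_stream()].
#' @param path File path.
#' @param fs,channel,units Stream metadata to attach on read (the CSV itself
#'   carries only the two columns).
#' @return `write_stream_csv` returns `path` invisibly; `read_stream_csv`
#'   returns a [sensor_stream()].
#' @export
write_stream_csv <- function(stream, path) {
  stopifnot(is_sensor_stream(stream))
  utils::write.csv(as.data.frame(stream)[, c("t_s", "value")], path,
    row.names = FALSE, quote = FALSE, fileEncoding = "UTF-8"
  )
  invisible(path)
}

#' @rdname write_stream_csv
#' @export
read_stream_csv <- function(path, fs, channel = "signal", units = "") {
  df <- utils::read.csv(path, fileEncoding = "UTF-8")
  if (!all(c("t_s", "value") %in% names(df))) {
    stop("invalid-argument: stream CSV must have columns 't_s' and 'value'")
  }
  sensor_stream(df$t_s, df$value, fs = fs, channel = channel, units = units)
}
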