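#' Build the alternating FOT/RESMON measurement timeline
#'
#' Constructs the deterministic two-hour protocol schedule: each measurement
#' session is a 2-min forced-oscillation (FOT) measurement, a 5-min rest, a
#' 1-min RESMON measurement and another 5-min rest; the cycle repeats for
#' `n_sessions` sessions and the final rest of the last session is omitted.
#' With the defaults this gives ten 13-min sessions whose last one lasts
#' 8 min, 125 min in total.
#'
#' @param n_sessions Number of measurement sessions (default 10).
#' @param fot_min FOT measurement duration in minutes (default 2).
#' @param rest_min Rest duration in minutes (default 5), used twice per
#'   session.
#' @param resmon_min RESMON measurement duration in minutes (default 1).
#' @return A `protocol_timeline`: a list with `events` (data frame with
#'   columns `kind`, `session_index`, `start`, `end`, all times in minutes
#'   from the protocol origin = start of the first FOT measurement),
#'   `n_sessions` and `total_duration` (minutes).
#' @examples
#' tl <- build_timeline()
#' tl$total_duration # 125
#' @export
build_timeline <- function(n_sessions = 10, fot_min = 2, rest_min = 5,
                           resmon_min = 1) {
  if (!is.numeric(n_sessions) || n_sessions < 1 || n_sessions != round(n_sessions)) {
    stop("invalid-argument: 'n_sessions' must be a positive integer")
  }
  if (fot_min <= 0 || rest_min <= 0 || resmon_min <= 0) {
    stop("invalid-argument: all durations must be positive")
  }
  n_sessions <- as.integer(n_sessions)
  cycle <- fot_min + rest_min + resmon_min + rest_min
  rows <- vector("list", n_sessions)
  for (s in seq_len(n_sessions)) {
    o <- (s - 1) * cycle
    ev <- data.frame(
      kind = c("FOT", "REST", "RESMON", "REST"),
      session_index = s,
      start = o + c(0, fot_min, fot_min + rest_min, fot_min + rest_min + resmon_min),
      end = o + c(fot_min, fot_min + rest_min, fot_min + rest_min + resmon_min, cycle)
    )
    if (s == n_sessions) ev <- ev[-4L, ] # final rest omitted
    rows[[s]] <- ev
  }
  events <- do.call(rbind, rows)
  rownames(events) <- NULL
  structure(
    list(
      events = events,
      n_sessions = n_sessions,
      total_duration = (n_sessions - 1) * cycle + fot_min + rest_min + resmon_min
    ),
    class = "protocol_timeline"
  )
}

#' @export
print.protocol_timeline <- function(x, ...) {
  cat(sprintf(
    "<protocol_timeline> %d sessions, %g min total, %d events\n",
    x$n_sessions, x$total_duration, nrow(x$events)
  ))
  invisible(x)
}

#' Interval between successive measurements of one device
#'
#' The prediction horizon of the forecasting scheme equals the gap between
#' the end of one device measurement and the start of the next one for that
#' device: 11 min for FOT and 12 min for RESMON under the default protocol.
#'
#' @param timeline A [build_timeline()] result.
#' @param device `"FOT"` or `"RESMON"`.
#' @return The constant inter-measurement gap in minutes.
#' @export
inter_measurement_interval <- function(timeline, device = c("FOT", "RESMON")) {
  stopifnot(inherits(timeline, "protocol_timeline"))
  device <- match.arg(device)
  if (timeline$n_sessions < 2) {
    stop("invalid-argument: timeline must have at least 2 sessions")
  }
  ev <- timeline$events[timeline$events$kind == device, ]
  gaps <- ev$start[-1L] - ev$end[-nrow(ev)]
  if (diff(range(gaps)) > 1e-9) {
    stop("internal error: inter-measurement gap is not constant")
  }
  gaps[1L]
}

#' Wearable-sensor extraction windows
#'
#' Returns the 2-min windows over which the continuously recorded wearable
#' (EQV) streams are extracted for synchronization with the discrete lung
#' function measurements: one window per session, co-timed with that
#' session's FOT measurement (2-min extraction + 11-min pause matches the
#' 13-min session cycle).
#'
#' @param timeline A [build_timeline()] result.
#' @return Data frame of events with `kind = "EQV_EXTRACT"`, one per session.
#' @export
eqv_extraction_windows <- function(timeline) {
  stopifnot(inherits(timeline, "protocol_timeline"))
  ev <- timeline$events[timeline$events$kind == "FOT", ]
  out <- data.frame(
    kind = "EQV_EXTRACT",
    session_index = ev$session_index,
    start = ev$start,
    end = ev$end
  )
  rownames(out) <- NULL
  out
}

#' Align a continuous stream with protocol windows
#'
#' Slices a stream into one segment per window using half-open intervals
#' `[start, end)` in seconds (`window minutes * 60`), so at integer sampling
#' rates every segment has exactly `rate * duration` samples and segments of
#' adjacent windows never share a sample.
#'
#' @param stream A [sensor_stream()] covering all windows.
#' @param windows Data frame of protocol events (columns `session_index`,
#'   `start`, `end` in minutes), e.g. from [eqv_extraction_windows()].
#' @return A list of [sensor_stream()] segments, one per window, each with a
#'   `session_index` attribute.
#' @export
align_stream <- function(stream, windows) {
  stopifnot(is_sensor_stream(stream))
  if (nrow(stream) == 0L) stop("invalid-argument: empty stream")
  fs <- attr(stream, "fs")
  last_end_s <- max(windows$end) * 60
  deficit <- last_end_s - (max(stream$t_s) + 1 / fs)
  if (deficit > 1e-9) {
    stop(sprintf(
      "coverage error: stream ends %.3f s before the last window end (%.1f s)",
      deficit, last_end_s
    ))
  }
  lapply(seq_len(nrow(windows)), function(i) {
    lo <- windows$start[i] * 60
    hi <- windows$end[i] * 60
    keep <- stream$t_s >= lo & stream$t_s < hi
    seg <- sensor_stream(stream$t_s[keep], stream$value[keep],
      fs = fs, channel = attr(stream, "channel"), units = attr(stream, "units")
    )
    attr(seg, "session_index") <- windows$session_index[i]
    seg
  })
}

#' Read and write a protocol timeline as JSON
#'
#' @param timeline A [build_timeline()] result.
#' @param path File path.
#' @return `write_timeline_json` returns `path` invisibly;
#'   `read_timeline_json` returns a `protocol_timeline` identical to the one
#'   written (bit-exact round trip).
#' @export
write_timeline_json <- function(timeline, path) {
  stopifnot(inherits(timeline, "protocol_timeline"))
  jsonlite::write_json(
    list(
      n_sessions = timeline$n_sessions,
      total_duration = timeline$total_duration,
      events = timeline$events
    ),
    path,
    auto_unbox = TRUE, digits = NA
  )
  invisible(path)
}

#' @rdname write_timeline_json
#' @export
read_timeline_json <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  structure(
    list(
      events = as.data.frame(x$events),
      n_sessions = as.integer(x$n_sessions),
      total_duration = x$total_duration
    ),
    class = "protocol_timeline"
  )
}
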