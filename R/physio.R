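#' Detect systolic peaks in a pulse-oximeter recording
#'
#' Local maxima above an adaptive amplitude threshold (midway between the
#' median and the 99th percentile of the trace), separated by at least
#' `min_interval`; of two candidates closer than that, the larger is kept.
#'
#' @param rec A [sampled_series()] sampled at >= 100 Hz.
#' @param min_interval Minimum beat separation in seconds (\[0.25, 2\]).
#' @param lowpass_hz Zero-phase pre-filter corner (default 10 Hz) that strips
#'   sensor noise without moving the systolic peak.
#' @return An [event_series()] of kind `"pulse-peak"`.
#' @export
detect_pulse_peaks <- function(rec, min_interval = 0.4, lowpass_hz = 10) {
  stopifnot(inherits(rec, "sampled_series"))
  if (rec$dt > 0.01) {
    stop("sampling too coarse for beat detection (need >= 100 Hz)", call. = FALSE)
  }
  if (min_interval < 0.25 || min_interval > 2) {
    stop("`min_interval` must lie in [0.25, 2] s", call. = FALSE)
  }
  v <- rec$values
  if (diff(range(v)) < 1e-9) stop("flat trace: no pulse events", call. = FALSE)
  ny <- 1 / (2 * rec$dt)
  if (lowpass_hz < ny) {
    v <- signal::filtfilt(signal::butter(4, lowpass_hz / ny, type = "low"), v)
  }
  thr <- stats::median(v) + 0.5 * (stats::quantile(v, 0.99, names = FALSE) - stats::median(v))
  pk <- pracma::findpeaks(v, minpeakheight = thr,
                          minpeakdistance = max(1L, round(min_interval / rec$dt)))
  if (is.null(pk) || nrow(pk) == 0) stop("no pulse events detected", call. = FALSE)
  idx <- sort(pk[, 2])
  event_series(rec$t0 + (idx - 1) * rec$dt, kind = "pulse-peak")
}

#' Frame-aligned heartbeat-interval series
#'
#' For each imaging frame time, collects the beat-to-beat durations whose
#' midpoints fall in a `window`-second window centred on the frame, averages
#' them and (by default) returns the inverse of that average. Frames whose
#' window contains no beat duration are filled with the nearest valid value
#' and flagged.
#'
#' @param peaks [event_series()] of pulse peaks (>= 2 events).
#' @param frame_times Numeric vector of frame-centre times in seconds.
#' @param window Sliding-window width in seconds (default 6).
#' @param form `"inverse"` (default: 1 / mean duration, a beat rate in 1/s,
#'   following the processing convention) or `"interval"` (the mean duration
#'   itself, in s). Coherence band structure is essentially identical for the
#'   two at physiological modulation depths; both are exposed.
#' @return A [sampled_series()] at the frame spacing, with attribute
#'   `qc_filled` marking frames that had no in-window duration.
#' @export
compute_hbi <- function(peaks, frame_times, window = 6,
                        form = c("inverse", "interval")) {
  form <- match.arg(form)
  stopifnot(inherits(peaks, "event_series"))
  if (length(peaks$times) < 2) stop("need at least 2 peaks", call. = FALSE)
  durs <- diff(peaks$times)
  mids <- peaks$times[-length(peaks$times)] + durs / 2
  vals <- vapply(frame_times, function(t) {
    sel <- mids >= t - window / 2 & mids <= t + window / 2
    if (!any(sel)) NA_real_ else mean(durs[sel])
  }, numeric(1))
  filled <- is.na(vals)
  if (all(filled)) stop("no beat durations fall in any frame window", call. = FALSE)
  if (any(filled)) {
    ok <- which(!filled)
    near <- ok[vapply(which(filled), function(i) which.min(abs(ok - i)), integer(1))]
    vals[filled] <- vals[near]
  }
  if (form == "inverse") vals <- 1 / vals
  dt <- if (length(frame_times) > 1) frame_times[2] - frame_times[1] else 1
  out <- sampled_series(vals, dt = dt, t0 = frame_times[1], label = "HBI")
  attr(out, "qc_filled") <- filled
  out
}

#' Detect breath maxima and minima in a bellows recording
#'
#' The trace is zero-phase low-pass filtered at 1 Hz (4th-order Butterworth,
#' forward-backward) to strip sensor ripple without shifting extrema, then
#' alternating local maxima and minima are extracted; of two consecutive
#' same-kind extrema, the lesser maximum (or greater minimum) is dropped to
#' enforce strict alternation.
#'
#' @param rec A [sampled_series()] covering at least two breaths.
#' @param lowpass_hz Low-pass corner frequency (default 1 Hz).
#' @return List with [event_series()] elements `maxima` and `minima`.
#' @export
detect_breath_extrema <- function(rec, lowpass_hz = 1) {
  stopifnot(inherits(rec, "sampled_series"))
  v <- rec$values
  if (diff(range(v)) < 1e-9) stop("flat trace: no breath events", call. = FALSE)
  ny <- 1 / (2 * rec$dt)
  if (lowpass_hz < ny) {
    bf <- signal::butter(4, lowpass_hz / ny, type = "low")
    # demean before filtering so a baseline offset cannot excite edge
    # transients (keeps RVT exactly offset-invariant)
    mu <- mean(v)
    v <- signal::filtfilt(bf, v - mu) + mu
  }
  dv <- diff(v)
  s <- sign(dv)
  s[s == 0] <- 1
  turns <- which(diff(s) != 0) + 1L
  if (!length(turns)) stop("monotone trace: no breath events", call. = FALSE)
  kind <- ifelse(diff(s)[turns - 1L] < 0, "max", "min")
  # enforce strict alternation, keeping the more extreme of same-kind runs
  keep_idx <- integer(0)
  keep_kind <- character(0)
  for (k in seq_along(turns)) {
    if (length(keep_kind) && keep_kind[length(keep_kind)] == kind[k]) {
      prev <- keep_idx[length(keep_idx)]
      better <- if (kind[k] == "max") v[turns[k]] > v[prev] else v[turns[k]] < v[prev]
      if (better) keep_idx[length(keep_idx)] <- turns[k]
    } else {
      keep_idx <- c(keep_idx, turns[k])
      keep_kind <- c(keep_kind, kind[k])
    }
  }
  tt <- rec$t0 + (keep_idx - 1) * rec$dt
  is_max <- keep_kind == "max"
  if (!any(is_max) || all(is_max)) stop("no alternating breath extrema found", call. = FALSE)
  list(
    maxima = event_series(tt[is_max], v[keep_idx[is_max]], kind = "breath-max"),
    minima = event_series(tt[!is_max], v[keep_idx[!is_max]], kind = "breath-min")
  )
}

#' Frame-aligned respiration-volume-per-time series
#'
#' Each breath maximum is paired with the next minimum; the breath's value is
#' (max amplitude - min amplitude) divided by the spacing to the following
#' maximum, assigned at the maximum's time, then linearly interpolated to the
#' frame times (boundary values held beyond the first/last breath).
#'
#' @param maxima,minima [event_series()] of breath extrema (alternating).
#' @param frame_times Frame-centre times in seconds.
#' @return A [sampled_series()] at the frame spacing.
#' @export
compute_rvt <- function(maxima, minima, frame_times) {
  stopifnot(inherits(maxima, "event_series"), inherits(minima, "event_series"))
  if (length(maxima$times) < 2) stop("fewer than 2 breath maxima", call. = FALSE)
  if (is.null(maxima$amplitudes) || is.null(minima$amplitudes)) {
    stop("breath extrema need amplitudes", call. = FALSE)
  }
  tmax <- maxima$times
  vals <- numeric(0)
  at <- numeric(0)
  for (i in seq_len(length(tmax) - 1)) {
    nxt <- which(minima$times > tmax[i])
    if (!length(nxt)) next
    j <- nxt[1]
    vals <- c(vals, (maxima$amplitudes[i] - minima$amplitudes[j]) /
                (tmax[i + 1] - tmax[i]))
    at <- c(at, tmax[i])
  }
  if (length(vals) < 1) stop("fewer than 2 usable breaths", call. = FALSE)
  out <- if (length(vals) == 1) rep(vals, length(frame_times)) else
    stats::approx(at, vals, xout = frame_times, rule = 2)$y
  dt <- if (length(frame_times) > 1) frame_times[2] - frame_times[1] else 1
  sampled_series(out, dt = dt, t0 = frame_times[1], label = "RVT")
}

#' Mean-normalize a series
#'
#' Default subtracts the temporal mean (output mean exactly 0); `"divide"`
#' rescales to mean 1 (percent-change form). Wavelet coherence is invariant
#' to either choice (it is affine-invariant), so the switch only affects the
#' series' units.
#'
#' @param x A [sampled_series()].
#' @param mode `"subtract"` (default) or `"divide"`.
#' @return A [sampled_series()].
#' @export
mean_normalize <- function(x, mode = c("subtract", "divide")) {
  mode <- match.arg(mode)
  stopifnot(inherits(x, "sampled_series"))
  mu <- mean(x$values)
  v <- if (mode == "subtract") {
    x$values - mu
  } else {
    if (abs(mu) < 1e-12) stop("cannot divide-normalize a zero-mean series", call. = FALSE)
    x$values / mu
  }
  sampled_series(v, dt = x$dt, t0 = x$t0, label = x$label)
}

#' Read / write two-column physiological recordings
#'
#' Plain tab-separated text with a `time_s` / `value` header, one row per
#' sample at the peripheral sampling rate.
#'
#' @param path File path.
#' @return [read_physio_recording()]: a [sampled_series()].
#' @export
read_physio_recording <- function(path) {
  d <- utils::read.table(path, header = TRUE, sep = "\t")
  dt <- stats::median(diff(d$time_s))
  sampled_series(d$value, dt = dt, t0 = d$time_s[1], label = basename(path))
}

#' @rdname read_physio_recording
#' @param x A [sampled_series()] to write.
#' @export
write_physio_recording <- function(x, path) {
  stopifnot(inherits(x, "sampled_series"))
  utils::write.table(
    data.frame(time_s = sprintf("%.6f", series_times(x)),
               value = sprintf("%.6g", x$values)),
    path, sep = "\t", row.names = FALSE, quote = FALSE
  )
  invisible(path)
}

#' Read a frames x networks BOLD table
#'
#' Tab-separated with a header row of network labels, one row per frame.
#'
#' @param path File path.
#' @param dt Frame spacing in seconds.
#' @return Named list of [sampled_series()], one per network column.
#' @export
read_bold_table <- function(path, dt = 0.72) {
  d <- utils::read.table(path, header = TRUE, sep = "\t")
  out <- lapply(names(d), function(nm) sampled_series(d[[nm]], dt = dt, label = nm))
  names(out) <- names(d)
  out
}

#' Write a frame-aligned physiological series with QC flags
#'
#' Tab-separated `(frame_time_s, value, qc_flag)`.
#'
#' @param x A [sampled_series()] (e.g. from [compute_hbi()]).
#' @param path Output path.
#' @export
write_frame_series <- function(x, path) {
  qc <- attr(x, "qc_filled")
  if (is.null(qc)) qc <- rep(FALSE, length(x$values))
  utils::write.table(
    data.frame(frame_time_s = series_times(x), value = x$values,
               qc_flag = as.integer(qc)),
    path, sep = "\t", row.names = FALSE, quote = FALSE
  )
  invisible(path)
}
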