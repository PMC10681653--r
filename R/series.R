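#' Uniformly sampled timeseries
#'
#' The basic container used throughout the package: a real-valued signal
#' sampled at a fixed step `dt` starting at time `t0`.
#'
#' @param values Numeric vector of samples (finite).
#' @param dt Sampling step in seconds (> 0).
#' @param t0 Time of the first sample in seconds.
#' @param label Optional text label carried through the pipeline.
#'
#' @return An object of class `sampled_series` with fields `values`, `dt`,
#'   `t0` and `label`.
#' @export
sampled_series <- function(values, dt, t0 = 0, label = "") {
  values <- as.numeric(values)
  if (!is.numeric(dt) || length(dt) != 1L || !is.finite(dt) || dt <= 0) {
    stop("`dt` must be a single positive number", call. = FALSE)
  }
  if (anyNA(values) || any(!is.finite(values))) {
    stop("`values` must be finite", call. = FALSE)
  }
  structure(
    list(values = values, dt = dt, t0 = as.numeric(t0), label = as.character(label)),
    class = "sampled_series"
  )
}

#' @export
print.sampled_series <- function(x, ...) {
  cat(sprintf(
    "<sampled_series> %s: %d samples, dt = %g s, span [%.3f, %.3f] s\n",
    if (nzchar(x$label)) x$label else "(unlabelled)",
    length(x$values), x$dt, x$t0, x$t0 + (length(x$values) - 1) * x$dt
  ))
  invisible(x)
}

#' @export
length.sampled_series <- function(x) length(x$values)

#' Sample times of a series
#'
#' @param x A `sampled_series`.
#' @return Numeric vector of sample times in seconds.
#' @export
series_times <- function(x) {
  stopifnot(inherits(x, "sampled_series"))
  x$t0 + (seq_along(x$values) - 1) * x$dt
}

#' Event times detected in a recording
#'
#' Holds strictly increasing event times (pulse peaks, breath maxima or
#' minima), with optional amplitudes for breath extrema.
#'
#' @param times Strictly increasing event times in seconds.
#' @param amplitudes Optional numeric amplitudes, same length as `times`.
#' @param kind One of `"pulse-peak"`, `"breath-max"`, `"breath-min"`.
#' @return An object of class `event_series`.
#' @export
event_series <- function(times, amplitudes = NULL,
                         kind = c("pulse-peak", "breath-max", "breath-min")) {
  kind <- match.arg(kind)
  times <- as.numeric(times)
  if (length(times) && any(diff(times) <= 0)) {
    stop("event times must be strictly increasing", call. = FALSE)
  }
  if (!is.null(amplitudes)) {
    amplitudes <- as.numeric(amplitudes)
    if (length(amplitudes) != length(times) || any(!is.finite(amplitudes))) {
      stop("amplitudes must be finite and match `times` in length", call. = FALSE)
    }
  }
  structure(list(times = times, amplitudes = amplitudes, kind = kind),
            class = "event_series")
}

#' @export
print.event_series <- function(x, ...) {
  cat(sprintf("<event_series> %s: %d events", x$kind, length(x$times)))
  if (length(x$times)) {
    cat(sprintf(" over [%.2f, %.2f] s", x$times[1], x$times[length(x$times)]))
  }
  cat("\n")
  invisible(x)
}

#' @export
length.event_series <- function(x) length(x$times)

# Run expr under a fixed RNG seed when one is given, leaving the global RNG
# state untouched; NULL means use the current stream.
with_seed_if <- function(seed, expr) {
  if (is.null(seed)) expr else withr::with_seed(as.integer(seed), expr)
}

# Wrap angles into (-pi, pi].
wrap_phase <- function(phi) {
  out <- (phi + pi) %% (2 * pi) - pi
  out[out <= -pi] <- pi
  out
}
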