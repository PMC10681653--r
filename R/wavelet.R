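#' Complex Morlet mother wavelet
#'
#' \eqn{\psi_0(\eta) = \pi^{-1/4} e^{i \omega_0 \eta} e^{-\eta^2/2}}, the
#' standard unit-energy complex Morlet wavelet. With the default
#' \eqn{\omega_0 = 6} the Fourier period of scale \eqn{s} is
#' \eqn{T \approx 1.033\,s}, so scale and period axes are near-interchangeable.
#'
#' @param eta Dimensionless time (numeric vector).
#' @param omega0 Dimensionless centre frequency (default 6).
#' @return Complex vector of wavelet values.
#' @export
morlet <- function(eta, omega0 = 6) {
  stopifnot(is.numeric(omega0), length(omega0) == 1L, omega0 > 0)
  pi^(-1 / 4) * exp(1i * omega0 * eta) * exp(-eta^2 / 2)
}

#' Fourier-period-to-scale ratio of the Morlet wavelet
#'
#' @param omega0 Dimensionless centre frequency.
#' @return The factor \eqn{4\pi / (\omega_0 + \sqrt{2 + \omega_0^2})}
#'   converting scale (s) to Fourier period (s); about 1.033 at
#'   \eqn{\omega_0 = 6}.
#' @export
morlet_fourier_factor <- function(omega0 = 6) {
  4 * pi / (omega0 + sqrt(2 + omega0^2))
}

#' Logarithmic scale grid for the continuous wavelet transform
#'
#' Builds the dyadic scale discretisation \eqn{s_j = s_0 2^{j \cdot dj}} used
#' by all transforms, together with the matching Fourier periods and
#' frequencies.
#'
#' @param dt Sampling step in seconds.
#' @param n Series length (>= 64).
#' @param dj Scale spacing in octaves per voice (default 1/12, i.e. 12 voices
#'   per octave).
#' @param s0 Smallest scale in seconds (default `2 * dt`).
#' @param max_period Largest Fourier period retained (default `n * dt / 2`,
#'   half the record).
#' @param omega0 Morlet centre frequency.
#' @return An object of class `scale_grid` with fields `scales`,
#'   `fourier_periods`, `frequencies` (Hz), `dj`, `s0`, `omega0`,
#'   `fourier_factor`, `dt`, `n`.
#' @export
build_scale_grid <- function(dt, n, dj = 1 / 12, s0 = 2 * dt,
                             max_period = n * dt / 2, omega0 = 6) {
  stopifnot(dt > 0, n >= 64, dj > 0, max_period > 0)
  if (s0 < dt) {
    stop("`s0` must be at least one sample step `dt`", call. = FALSE)
  }
  ff <- morlet_fourier_factor(omega0)
  max_scale <- max_period / ff
  if (max_scale < s0) stop("`max_period` is below the smallest resolvable period", call. = FALSE)
  jmax <- floor(log2(max_scale / s0) / dj)
  scales <- s0 * 2^((0:jmax) * dj)
  structure(
    list(
      scales = scales,
      fourier_periods = ff * scales,
      frequencies = 1 / (ff * scales),
      dj = dj, s0 = s0, omega0 = omega0,
      fourier_factor = ff, dt = dt, n = as.integer(n)
    ),
    class = "scale_grid"
  )
}

#' @export
print.scale_grid <- function(x, ...) {
  cat(sprintf(
    "<scale_grid> %d scales, periods %.3f-%.1f s (%.4f-%.4f Hz), dj = %g, omega0 = %g\n",
    length(x$scales), x$fourier_periods[1],
    x$fourier_periods[length(x$fourier_periods)],
    max(x$frequencies), min(x$frequencies), x$dj, x$omega0
  ))
  invisible(x)
}

#' Cone of influence
#'
#' Per-time maximum trustworthy Fourier period. Edge effects contaminate
#' wavelet estimates within one e-folding time (\eqn{\sqrt{2} s}) of either
#' record edge, so a point at time t supports periods up to
#' `fourier_factor * min(t - t_first, t_last - t) / sqrt(2)`.
#'
#' @param n Number of samples (>= 2).
#' @param dt Sampling step (s).
#' @param t0 Time of the first sample (s).
#' @param omega0 Morlet centre frequency.
#' @return Numeric vector of length `n`: the largest trustworthy Fourier
#'   period (s) at each sample time; 0 at the record edges.
#' @export
cone_of_influence <- function(n, dt, t0 = 0, omega0 = 6) {
  stopifnot(n >= 2, dt > 0)
  tt <- t0 + (seq_len(n) - 1) * dt
  edge_dist <- pmin(tt - tt[1], tt[n] - tt)
  morlet_fourier_factor(omega0) * edge_dist / sqrt(2)
}

# Precompute everything reusable across transforms of series with the same
# (n, dt, grid): padded length, per-scale wavelet kernel FFTs, per-scale
# time-smoothing kernel FFTs and edge-renormalisation denominators, and the
# scale-direction boxcar smoothing matrix. Used heavily by the bootstrap
# loops, where hundreds of transforms share one plan.
wtc_plan <- function(grid, n = grid$n, dt = grid$dt, smooth_dj0 = 0.6) {
  n <- as.integer(n)
  ns <- length(grid$scales)
  npad <- 2^ceiling(log2(2 * n))

  # wavelet kernels: h_s[m] = sqrt(dt/s) * psi0(m * dt / s), m wrapped
  m <- c(0:(npad / 2), (-npad / 2 + 1):(-1))
  kern <- matrix(0i, nrow = npad, ncol = ns)
  for (j in seq_len(ns)) {
    s <- grid$scales[j]
    kern[, j] <- sqrt(dt / s) * morlet(m * dt / s, grid$omega0)
  }
  kern_fft <- Conj(stats::mvfft(kern))

  # time-smoothing kernels: Gaussian, sd = s / sqrt(2) seconds, truncated at
  # +/- 4 sd; stored as wrapped FFTs at a padded length that prevents the
  # circular convolution from mixing the two record ends.
  half <- pmin(ceiling(4 * grid$scales / (sqrt(2) * dt)), n - 1L)
  lpad <- 2^ceiling(log2(n + max(half) + 1))
  ms <- c(0:(lpad / 2), (-lpad / 2 + 1):(-1))
  skern <- matrix(0, nrow = lpad, ncol = ns)
  for (j in seq_len(ns)) {
    sd_samp <- grid$scales[j] / (sqrt(2) * dt)
    w <- exp(-0.5 * (ms / sd_samp)^2)
    w[abs(ms) > half[j]] <- 0
    skern[, j] <- w / sum(w)
  }
  skern_fft <- Conj(stats::mvfft(skern))

  # edge renormalisation: smoothing of an all-ones field, so that the
  # truncated kernels keep unit mass everywhere (constant in -> constant out)
  ones <- matrix(0, nrow = lpad, ncol = ns)
  ones[seq_len(n), ] <- 1
  denom <- Re(stats::mvfft(stats::mvfft(ones) * skern_fft, inverse = TRUE))[seq_len(n), , drop = FALSE] / lpad

  # scale-direction boxcar: total width smooth_dj0 / dj voices, fractional
  # ends, rows renormalised at the grid boundary
  width <- smooth_dj0 / grid$dj
  smat <- diag(ns)
  if (width > 1) {
    k <- floor((width - 1) / 2)
    frac <- (width - (2 * k + 1)) / 2
    offs <- -(k + 1):(k + 1)
    wts <- c(frac, rep(1, 2 * k + 1), frac)
    smat <- matrix(0, ns, ns)
    for (j in seq_len(ns)) {
      idx <- j + offs
      ok <- idx >= 1 & idx <= ns
      smat[j, idx[ok]] <- wts[ok] / sum(wts[ok])
    }
  }

  list(
    grid = grid, n = n, dt = dt, npad = npad, kern_fft = kern_fft,
    lpad = lpad, skern_fft = skern_fft, denom = t(denom), smat = smat,
    coi = cone_of_influence(n, dt, 0, grid$omega0)
  )
}

cwt_with_plan <- function(values, plan) {
  n <- plan$n
  xpad <- numeric(plan$npad)
  xpad[seq_len(n)] <- values - mean(values)
  xhat <- stats::fft(xpad)
  W <- stats::mvfft(xhat * plan$kern_fft, inverse = TRUE)[seq_len(n), , drop = FALSE] / plan$npad
  t(W) # scales x time
}

# Smooth a (scales x time) field: Gaussian in time (per scale), boxcar in
# scale, both unit-mass with edge renormalisation.
smooth_with_plan <- function(field, plan) {
  n <- plan$n
  fp <- matrix(0i, nrow = plan$lpad, ncol = nrow(field))
  fp[seq_len(n), ] <- t(field)
  sm <- stats::mvfft(stats::mvfft(fp) * plan$skern_fft, inverse = TRUE)[seq_len(n), , drop = FALSE] / plan$lpad
  sm <- t(sm) / plan$denom
  plan$smat %*% sm
}

#' Continuous Morlet wavelet transform
#'
#' Computes the CWT
#' \eqn{W_X(n, s) = \sqrt{\Delta t / s} \sum_{n'} x_{n'}
#' \psi_0^*((n'-n)\Delta t / s)} at every scale of `grid`, via FFT
#' convolution with zero-padding to the next power of two (at least twice the
#' record length, so the circular product reproduces the direct sum exactly).
#' The series mean is removed first.
#'
#' @param x A [sampled_series()].
#' @param grid A [build_scale_grid()] grid built for `length(x)` and `x$dt`.
#' @return An object of class `cwt_field`: complex `coeffs`
#'   (scales x time), the `grid`, sample `times`, `dt` and the per-time cone
#'   of influence `coi_period`.
#' @export
cwt <- function(x, grid) {
  stopifnot(inherits(x, "sampled_series"), inherits(grid, "scale_grid"))
  if (length(x$values) != grid$n || abs(x$dt - grid$dt) > 1e-12) {
    stop("series length/dt do not match the scale grid", call. = FALSE)
  }
  plan <- wtc_plan(grid)
  structure(
    list(
      coeffs = cwt_with_plan(x$values, plan),
      grid = grid,
      times = series_times(x),
      dt = x$dt,
      coi_period = cone_of_influence(grid$n, x$dt, x$t0, grid$omega0)
    ),
    class = "cwt_field"
  )
}

#' @export
print.cwt_field <- function(x, ...) {
  cat(sprintf("<cwt_field> %d scales x %d times, dt = %g s\n",
              nrow(x$coeffs), ncol(x$coeffs), x$dt))
  invisible(x)
}

#' Cross-wavelet transform
#'
#' Pointwise \eqn{W_{XY} = W_X W_Y^*}: the modulus is the joint power of the
#' two series, the argument their local phase difference. By the package's
#' convention the physiological signal is passed as `WX` and the BOLD signal
#' as `WY`, so a positive phase means the physiological signal leads.
#'
#' @param WX,WY `cwt_field` objects on identical grids and times.
#' @return An object of class `xwt_field` with complex `coeffs`, real
#'   `power`, `phase` in (-pi, pi], plus grid/times/cone.
#' @export
cross_wavelet <- function(WX, WY) {
  stopifnot(inherits(WX, "cwt_field"), inherits(WY, "cwt_field"))
  if (!isTRUE(all.equal(WX$grid$scales, WY$grid$scales)) ||
      !isTRUE(all.equal(WX$times, WY$times))) {
    stop("cross_wavelet: the two transforms are not on the same grid/times", call. = FALSE)
  }
  co <- WX$coeffs * Conj(WY$coeffs)
  structure(
    list(coeffs = co, power = Mod(co), phase = Arg(co),
         grid = WX$grid, times = WX$times, dt = WX$dt,
         coi_period = WX$coi_period),
    class = "xwt_field"
  )
}

#' Smooth a time-frequency field
#'
#' The smoothing operator used inside the coherence estimator: per scale a
#' unit-mass Gaussian in time of standard deviation \eqn{s/\sqrt{2}} seconds,
#' then a unit-mass boxcar across scales spanning `smooth_dj0` decorrelation
#' widths (`smooth_dj0 / dj` voices). Linear and positivity-preserving; a
#' constant field is returned unchanged.
#'
#' @param W Complex or real matrix (scales x time).
#' @param grid The matching `scale_grid`.
#' @param dt Sampling step (s).
#' @param smooth_dj0 Scale-smoothing span in decorrelation widths (default 0.6).
#' @return Matrix of the same shape.
#' @export
smooth_field <- function(W, grid, dt = grid$dt, smooth_dj0 = 0.6) {
  stopifnot(inherits(grid, "scale_grid"), nrow(W) == length(grid$scales))
  plan <- wtc_plan(grid, n = ncol(W), dt = dt, smooth_dj0 = smooth_dj0)
  out <- smooth_with_plan(W, plan)
  if (is.numeric(W)) Re(out) else out
}

wtc_from_cwt <- function(cx, cy, plan) {
  s_inv <- 1 / plan$grid$scales
  sxy <- smooth_with_plan(cx * Conj(cy) * s_inv, plan)
  sxx <- Re(smooth_with_plan(Mod(cx)^2 * s_inv, plan))
  syy <- Re(smooth_with_plan(Mod(cy)^2 * s_inv, plan))
  r2 <- Mod(sxy)^2 / (sxx * syy)
  list(r2 = r2, phase = Arg(sxy))
}

#' Wavelet transform coherence
#'
#' Magnitude-squared wavelet coherence
#' \deqn{R^2(n,s) = \frac{|S(s^{-1} W_{XY})|^2}
#'   {S(s^{-1}|W_X|^2)\, S(s^{-1}|W_Y|^2)}}
#' with \eqn{S} the [smooth_field()] operator; without smoothing the ratio is
#' identically 1. Phase is taken from the smoothed cross spectrum so that
#' coherence and phase refer to the same estimator. `x` is treated as the
#' physiological (signal-of-interest) series and `y` as the BOLD (reference)
#' series for the phase sign.
#'
#' @param x,y [sampled_series()] of equal length and `dt`, non-constant.
#' @param grid A [build_scale_grid()] for the common length/step.
#' @param smooth_dj0 Scale-smoothing span (see [smooth_field()]).
#' @return An object of class `coherence_field`: `r2` (clipped to \[0, 1\]),
#'   `phase` (radians, (-pi, pi]), `grid`, `times`, `coi_period`, and the
#'   attribute `preclip_range` recording the raw estimator's extremes.
#' @export
wtc <- function(x, y, grid, smooth_dj0 = 0.6) {
  stopifnot(inherits(x, "sampled_series"), inherits(y, "sampled_series"))
  if (length(x$values) != length(y$values) || abs(x$dt - y$dt) > 1e-12) {
    stop("`x` and `y` must share length and dt", call. = FALSE)
  }
  if (stats::sd(x$values) == 0 || stats::sd(y$values) == 0) {
    stop("degenerate (constant) input series", call. = FALSE)
  }
  if (length(x$values) != grid$n) {
    stop("series length does not match the scale grid", call. = FALSE)
  }
  plan <- wtc_plan(grid, smooth_dj0 = smooth_dj0)
  cx <- cwt_with_plan(x$values, plan)
  cy <- cwt_with_plan(y$values, plan)
  est <- wtc_from_cwt(cx, cy, plan)
  r2 <- est$r2
  preclip <- range(r2)
  r2 <- pmin(pmax(r2, 0), 1)
  dim(r2) <- dim(est$r2)
  structure(
    list(r2 = r2, phase = est$phase, grid = grid,
         times = x$t0 + (seq_len(grid$n) - 1) * x$dt, dt = x$dt,
         coi_period = cone_of_influence(grid$n, x$dt, x$t0, grid$omega0),
         smooth_dj0 = smooth_dj0,
         labels = c(x = x$label, y = y$label)),
    class = "coherence_field",
    preclip_range = preclip
  )
}

#' @export
print.coherence_field <- function(x, ...) {
  om <- out_of_cone(x)
  cat(sprintf(
    "<coherence_field> %d scales x %d times; mean out-of-cone R2 = %.3f (%d/%d points outside cone)\n",
    nrow(x$r2), ncol(x$r2), mean(x$r2[om]), sum(om), length(om)
  ))
  invisible(x)
}

#' Out-of-cone (trustworthy) mask of a time-frequency field
#'
#' @param field A `cwt_field`, `xwt_field` or `coherence_field`.
#' @return Logical matrix (scales x time), TRUE where the point's Fourier
#'   period is shorter than the cone-of-influence period, i.e. unaffected by
#'   edge effects.
#' @export
out_of_cone <- function(field) {
  outer(field$grid$fourier_periods, field$coi_period, `<`)
}

#' Heat-map rendering of a coherence field
#'
#' Draws R-squared over time and period (log axis), shades the cone of
#' influence and optionally outlines significant regions.
#'
#' @param x A `coherence_field`.
#' @param thresholds Optional [bootstrap_thresholds()] profile; significant
#'   regions are contoured at their per-scale threshold.
#' @param ... Passed to [graphics::image()].
#' @export
plot.coherence_field <- function(x, thresholds = NULL, ...) {
  per <- x$grid$fourier_periods
  graphics::image(x$times, log2(per), t(x$r2), zlim = c(0, 1),
                  xlab = "time (s)", ylab = "period (s), log2 axis",
                  yaxt = "n", ...)
  at <- pretty(log2(per))
  graphics::axis(2, at = at, labels = signif(2^at, 3))
  graphics::lines(x$times, log2(pmax(x$coi_period, per[1])), lty = 2)
  if (!is.null(thresholds)) {
    sig <- x$r2 > thresholds$r2_threshold & out_of_cone(x)
    graphics::contour(x$times, log2(per), t(sig * 1), levels = 0.5,
                      add = TRUE, drawlabels = FALSE)
  }
  invisible(x)
}

#' Export a coherence field as plain-text matrices
#'
#' Writes `<stem>_r2.tsv`, `<stem>_phase.tsv`, `<stem>_conemask.tsv` and a
#' JSON sidecar `<stem>_axes.json` holding the time, scale and frequency axes.
#'
#' @param coh A `coherence_field`.
#' @param stem Output path stem.
#' @return Invisibly, the sidecar path.
#' @export
write_coherence_field <- function(coh, stem) {
  wr <- function(m, suffix) {
    utils::write.table(m, paste0(stem, suffix), sep = "\t",
                       row.names = FALSE, col.names = FALSE)
  }
  wr(coh$r2, "_r2.tsv")
  wr(coh$phase, "_phase.tsv")
  wr(out_of_cone(coh) * 1L, "_conemask.tsv")
  sidecar <- paste0(stem, "_axes.json")
  jsonlite::write_json(
    list(times_s = coh$times, scales_s = coh$grid$scales,
         fourier_periods_s = coh$grid$fourier_periods,
         frequencies_hz = coh$grid$frequencies,
         coi_period_s = coh$coi_period, dj = coh$grid$dj,
         omega0 = coh$grid$omega0, smooth_dj0 = coh$smooth_dj0),
    sidecar, auto_unbox = TRUE, digits = NA
  )
  invisible(sidecar)
}
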