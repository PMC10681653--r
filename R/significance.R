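#' Fit an autoregressive model to a series
#'
#' Yule-Walker estimation of AR coefficients and innovation standard
#' deviation. Order 1 is the default null model for both BOLD and
#' physiological series; order 9 is supported as the higher-order variant for
#' cardiorespiratory series.
#'
#' @param x A [sampled_series()] (length > 10 * order, non-constant).
#' @param order Model order (positive integer).
#' @return An object of class `ar_model` with fields `order`,
#'   `coefficients`, `noise_sd`.
#' @export
fit_ar <- function(x, order = 1L) {
  stopifnot(inherits(x, "sampled_series"), order >= 1)
  v <- x$values
  if (length(v) <= 10 * order) stop("series too short for the requested order", call. = FALSE)
  if (stats::sd(v) == 0) stop("degenerate (constant) series", call. = FALSE)
  fit <- stats::ar.yw(v, aic = FALSE, order.max = order, demean = TRUE)
  coefs <- as.numeric(fit$ar)
  roots <- polyroot(c(1, -coefs))
  if (any(Mod(roots) <= 1 + 1e-10)) {
    stop("fitted AR model is not stationary", call. = FALSE)
  }
  structure(
    list(order = as.integer(order), coefficients = coefs,
         noise_sd = sqrt(max(fit$var.pred, 0))),
    class = "ar_model"
  )
}

#' @export
print.ar_model <- function(x, ...) {
  cat(sprintf("<ar_model> order %d: phi = (%s), innovation sd = %.4g\n",
              x$order, paste(signif(x$coefficients, 4), collapse = ", "),
              x$noise_sd))
  invisible(x)
}

#' Simulate from a fitted AR model
#'
#' Order-1 models start from the stationary distribution; higher orders use a
#' burn-in of `100 * order` samples.
#'
#' @param model An `ar_model`.
#' @param n Output length.
#' @param dt Sampling step (s).
#' @param seed Optional seed.
#' @return A [sampled_series()].
#' @export
simulate_ar <- function(model, n, dt = 1, seed = NULL) {
  stopifnot(inherits(model, "ar_model"))
  p <- model$order
  with_seed_if(seed, {
    if (p == 1L) {
      gen_ar1_series(model$coefficients, model$noise_sd, n, dt)
    } else {
      burn <- 100L * p
      eps <- stats::rnorm(n + burn, 0, model$noise_sd)
      v <- as.numeric(stats::filter(eps, model$coefficients, method = "recursive"))
      sampled_series(v[(burn + 1):(burn + n)], dt = dt, label = "ar sim")
    }
  })
}

#' Monte-Carlo per-scale significance thresholds for coherence magnitude
#'
#' Simulates `n_boot` independent pairs from the two fitted AR models,
#' computes wavelet coherence for each, pools the R-squared values per scale
#' across all out-of-cone time points and bootstrap pairs, and returns the
#' (1 - alpha) quantile at each scale. Scales with no out-of-cone points are
#' reported `NA`.
#'
#' @param model_x,model_y `ar_model` fits for the two signals.
#' @param n Analysis length (frames).
#' @param dt Frame spacing (s).
#' @param grid A [build_scale_grid()] for (n, dt).
#' @param n_boot Number of bootstrap pairs (default 300).
#' @param alpha Significance level (default 0.05).
#' @param seed Integer seed.
#' @param min_points Minimum pooled out-of-cone points for a scale's
#'   threshold to be reported (default 50).
#' @param smooth_dj0 Passed to the coherence estimator.
#' @return An object of class `threshold_profile`: per-scale `r2_threshold`,
#'   the grid, `alpha`, `n_boot`, `seed` and the AR models used.
#' @export
bootstrap_thresholds <- function(model_x, model_y, n, dt, grid,
                                 n_boot = 300, alpha = 0.05, seed = 1L,
                                 min_points = 50, smooth_dj0 = 0.6) {
  stopifnot(inherits(model_x, "ar_model"), inherits(model_y, "ar_model"))
  if (n_boot < 50) stop("`n_boot` below 50 gives unstable thresholds", call. = FALSE)
  if (n != grid$n || abs(dt - grid$dt) > 1e-12) {
    stop("(n, dt) do not match the scale grid", call. = FALSE)
  }
  plan <- wtc_plan(grid, smooth_dj0 = smooth_dj0)
  om <- outer(grid$fourier_periods, plan$coi, `<`)
  counts <- rowSums(om)
  ns <- length(grid$scales)
  r2mat <- with_seed_if(seed, {
    acc <- lapply(counts, function(k) numeric(k * n_boot))
    for (b in seq_len(n_boot)) {
      xs <- simulate_ar(model_x, n, dt)
      ys <- simulate_ar(model_y, n, dt)
      est <- wtc_from_cwt(cwt_with_plan(xs$values, plan),
                          cwt_with_plan(ys$values, plan), plan)
      for (j in seq_len(ns)) {
        if (counts[j] > 0) {
          acc[[j]][((b - 1) * counts[j] + 1):(b * counts[j])] <- est$r2[j, om[j, ]]
        }
      }
    }
    acc
  })
  thr <- vapply(seq_len(ns), function(j) {
    if (length(r2mat[[j]]) < min_points) NA_real_ else
      stats::quantile(pmin(r2mat[[j]], 1), 1 - alpha, names = FALSE)
  }, numeric(1))
  structure(
    list(r2_threshold = thr, grid = grid, alpha = alpha,
         n_boot = as.integer(n_boot), seed = as.integer(seed),
         model_x = model_x, model_y = model_y, smooth_dj0 = smooth_dj0,
         n_pooled = vapply(r2mat, length, integer(1))),
    class = "threshold_profile"
  )
}

#' @export
print.threshold_profile <- function(x, ...) {
  ok <- !is.na(x$r2_threshold)
  cat(sprintf(
    "<threshold_profile> alpha = %g, n_boot = %d; thresholds %.3f-%.3f over %d/%d scales\n",
    x$alpha, x$n_boot, min(x$r2_threshold[ok]), max(x$r2_threshold[ok]),
    sum(ok), length(ok)
  ))
  invisible(x)
}

#' Write a threshold profile as text
#'
#' Tab-separated `(scale_s, frequency_hz, r2_threshold)` plus a JSON sidecar
#' recording alpha, n_boot, seed and the AR fits.
#'
#' @param thr A `threshold_profile`.
#' @param stem Output path stem.
#' @export
write_threshold_profile <- function(thr, stem) {
  utils::write.table(
    data.frame(scale_s = thr$grid$scales, frequency_hz = thr$grid$frequencies,
               r2_threshold = thr$r2_threshold),
    paste0(stem, ".tsv"), sep = "\t", row.names = FALSE, quote = FALSE
  )
  jsonlite::write_json(
    list(alpha = thr$alpha, n_boot = thr$n_boot, seed = thr$seed,
         ar_x = unclass(thr$model_x), ar_y = unclass(thr$model_y)),
    paste0(stem, ".json"), auto_unbox = TRUE, digits = NA
  )
  invisible(stem)
}

#' Spectrum-preserving phase-shuffled surrogate
#'
#' Replaces the phases of the positive-frequency Fourier bins with i.i.d.
#' uniform(-pi, pi) draws (Hermitian symmetry enforced; the zero-frequency
#' and Nyquist bins are left untouched), then inverts the transform. The
#' output is real and has exactly the input's amplitude spectrum, so any
#' coherence with a partner signal reflects phase alignment only.
#'
#' @param x A [sampled_series()] of length >= 8.
#' @param seed Optional seed.
#' @return A [sampled_series()].
#' @export
make_phase_shuffled_null <- function(x, seed = NULL) {
  stopifnot(inherits(x, "sampled_series"))
  n <- length(x$values)
  if (n < 8) stop("series too short to phase-shuffle", call. = FALSE)
  X <- stats::fft(x$values)
  half <- if (n %% 2 == 0) n / 2 else (n - 1) / 2
  pos <- 2:half # exclude DC; exclude Nyquist bin when n is even
  if (n %% 2 == 1) pos <- 2:(half + 1)
  theta <- with_seed_if(seed, stats::runif(length(pos), -pi, pi))
  X[pos] <- Mod(X[pos]) * exp(1i * theta)
  X[n + 2 - pos] <- Conj(X[pos])
  out <- Re(stats::fft(X, inverse = TRUE)) / n
  sampled_series(out, dt = x$dt, t0 = x$t0,
                 label = paste0(x$label, " (phase-shuffled)"))
}
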