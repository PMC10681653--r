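#' Fit a first-order vector autoregression to a signal pair
#'
#' Ordinary least squares per equation on the demeaned pair:
#' `z[t] = A z[t-1] + e[t]`, `e ~ N(0, Sigma)`. Stationarity (spectral radius
#' of A below 1) is enforced; an effectively singular innovation covariance
#' (e.g. the two inputs identical) is rejected.
#'
#' @param x,y [sampled_series()] of equal length (> 20), non-constant.
#' @return An object of class `var_model` with fields `A` (2 x 2),
#'   `Sigma` (2 x 2), `means` (length 2).
#' @export
fit_var1 <- function(x, y) {
  stopifnot(inherits(x, "sampled_series"), inherits(y, "sampled_series"))
  if (length(x$values) != length(y$values)) stop("unequal lengths", call. = FALSE)
  n <- length(x$values)
  if (n <= 20) stop("series too short for a VAR(1) fit", call. = FALSE)
  if (stats::sd(x$values) == 0 || stats::sd(y$values) == 0) {
    stop("degenerate (constant) input", call. = FALSE)
  }
  Z <- cbind(x$values, y$values)
  mu <- colMeans(Z)
  Z <- sweep(Z, 2, mu)
  Y <- Z[-1, , drop = FALSE]
  X <- Z[-n, , drop = FALSE]
  A <- t(solve(crossprod(X), crossprod(X, Y)))
  if (max(Mod(eigen(A, only.values = TRUE)$values)) >= 1) {
    stop("fitted VAR(1) is not stationary", call. = FALSE)
  }
  resid <- Y - X %*% t(A)
  Sigma <- crossprod(resid) / (n - 1 - 2)
  ev <- eigen(Sigma, symmetric = TRUE, only.values = TRUE)$values
  if (min(ev) <= 1e-10 * max(ev)) {
    stop("singular innovation covariance (inputs linearly dependent)", call. = FALSE)
  }
  structure(list(A = A, Sigma = Sigma, means = mu, order = 1L),
            class = "var_model")
}

#' @export
print.var_model <- function(x, ...) {
  cat("<var_model> order 1\nA =\n")
  print(signif(x$A, 4))
  cat("Sigma =\n")
  print(signif(x$Sigma, 4))
  invisible(x)
}

#' Simulate a pair from a fitted VAR(1)
#'
#' Gaussian innovations drawn from the fitted covariance; a 200-sample
#' burn-in removes the arbitrary start.
#'
#' @param model A `var_model`.
#' @param n Output length.
#' @param dt Sampling step (s).
#' @param seed Optional seed.
#' @return List of two [sampled_series()].
#' @export
simulate_var1 <- function(model, n, dt = 1, seed = NULL) {
  stopifnot(inherits(model, "var_model"))
  burn <- 200L
  L <- chol(model$Sigma)
  with_seed_if(seed, {
    E <- matrix(stats::rnorm(2 * (n + burn)), ncol = 2) %*% L
    Z <- matrix(0, n + burn, 2)
    Z[1, ] <- E[1, ]
    for (t in 2:(n + burn)) Z[t, ] <- model$A %*% Z[t - 1, ] + E[t, ]
    Z <- Z[(burn + 1):(burn + n), ]
    list(x = sampled_series(Z[, 1], dt = dt, label = "var sim x"),
         y = sampled_series(Z[, 2], dt = dt, label = "var sim y"))
  })
}

#' Per-scale temporal variance of complex coherence
#'
#' Forms the complex coherence `z(t) = R^2(t) exp(i phi(t))` at each scale
#' over the out-of-cone times and returns its complex variance
#' `sigma^2 = < (z - mu)(z - mu)* >` (sample mean over time) - a real,
#' non-negative number that is zero iff coherence magnitude and phase are
#' constant in time. Scales with fewer than `min_points` out-of-cone times
#' are reported `NA`.
#'
#' @param coh A [wtc()] coherence field.
#' @param min_points Minimum out-of-cone times per scale (default 8).
#' @return Numeric vector, one value per scale.
#' @export
complex_wtc_variance <- function(coh, min_points = 8) {
  stopifnot(inherits(coh, "coherence_field"))
  om <- out_of_cone(coh)
  vapply(seq_len(nrow(coh$r2)), function(j) {
    sel <- om[j, ]
    if (sum(sel) < min_points) return(NA_real_)
    z <- coh$r2[j, sel] * exp(1i * coh$phase[j, sel])
    mean(Mod(z - mean(z))^2)
  }, numeric(1))
}

#' Test temporal variability of coherence against a stationary VAR(1) null
#'
#' Fits a VAR(1) to the pair, simulates `n_boot` bootstrap pairs from the
#' fit (which preserve the pair's stationary cross-dependence), computes the
#' per-scale complex-coherence variance for each, and flags the scales where
#' the observed variance exceeds the null's (1 - alpha) quantile - i.e.
#' where the coherence varies in time more than any stationary linear
#' relationship between the two signals would produce.
#'
#' @param x,y [sampled_series()] (see [fit_var1()] for preconditions).
#' @param grid A [build_scale_grid()] for the pair.
#' @param n_boot Number of bootstrap pairs (default 1000).
#' @param alpha Significance level (default 0.05).
#' @param seed Integer seed.
#' @param smooth_dj0 Passed to the coherence estimator.
#' @param min_points Passed to [complex_wtc_variance()].
#' @return An object of class `variability_profile`: per-scale `sigma2`,
#'   `threshold`, logical `significant`, the grid, `n_boot`, `alpha`, `seed`
#'   and the fitted `model`.
#' @export
variability_test <- function(x, y, grid, n_boot = 1000, alpha = 0.05,
                             seed = 1L, smooth_dj0 = 0.6, min_points = 8) {
  model <- fit_var1(x, y)
  plan <- wtc_plan(grid, smooth_dj0 = smooth_dj0)
  obs <- complex_wtc_variance(wtc(x, y, grid, smooth_dj0 = smooth_dj0),
                              min_points = min_points)
  om <- outer(grid$fourier_periods, plan$coi, `<`)
  sig2_of <- function(r2, phase) {
    vapply(seq_len(nrow(r2)), function(j) {
      sel <- om[j, ]
      if (sum(sel) < min_points) return(NA_real_)
      z <- pmin(r2[j, sel], 1) * exp(1i * phase[j, sel])
      mean(Mod(z - mean(z))^2)
    }, numeric(1))
  }
  null_mat <- with_seed_if(seed, {
    m <- matrix(NA_real_, length(grid$scales), n_boot)
    for (b in seq_len(n_boot)) {
      pair <- simulate_var1(model, grid$n, grid$dt)
      est <- wtc_from_cwt(cwt_with_plan(pair$x$values, plan),
                          cwt_with_plan(pair$y$values, plan), plan)
      m[, b] <- sig2_of(est$r2, est$phase)
    }
    m
  })
  thr <- apply(null_mat, 1, function(r) {
    if (all(is.na(r))) NA_real_ else stats::quantile(r, 1 - alpha, names = FALSE, na.rm = TRUE)
  })
  structure(
    list(sigma2 = obs, threshold = thr,
         significant = !is.na(obs) & !is.na(thr) & obs > thr,
         grid = grid, n_boot = as.integer(n_boot), alpha = alpha,
         seed = as.integer(seed), model = model),
    class = "variability_profile"
  )
}

#' @export
print.variability_profile <- function(x, ...) {
  cat(sprintf(
    "<variability_profile> %d scales, n_boot = %d; %d scales with significant temporal variability\n",
    length(x$sigma2), x$n_boot, sum(x$significant)
  ))
  invisible(x)
}

#' Percent of participants with significant temporal variability, per frequency
#'
#' @param profiles List of [variability_test()] profiles sharing one grid.
#' @return Data frame `(frequency_hz, pct_participants_significant, n)`.
#' @export
percent_participants_significant <- function(profiles) {
  if (!length(profiles)) stop("empty cohort", call. = FALSE)
  g <- profiles[[1]]$grid
  for (p in profiles) {
    if (!isTRUE(all.equal(p$grid$scales, g$scales))) {
      stop("profiles are on different scale grids", call. = FALSE)
    }
  }
  flags <- sapply(profiles, function(p) p$significant)
  data.frame(
    frequency_hz = g$frequencies,
    pct_participants_significant = 100 * rowMeans(flags),
    n = length(profiles)
  )
}

#' Write a variability profile as text
#'
#' Tab-separated `(frequency_hz, sigma2, threshold, significant, n_points)`.
#'
#' @param vp A `variability_profile`.
#' @param path Output path.
#' @export
write_variability_profile <- function(vp, path) {
  om <- outer(vp$grid$fourier_periods,
              cone_of_influence(vp$grid$n, vp$grid$dt, 0, vp$grid$omega0), `<`)
  utils::write.table(
    data.frame(frequency_hz = vp$grid$frequencies, sigma2 = vp$sigma2,
               threshold = vp$threshold, significant = vp$significant,
               n_points = rowSums(om)),
    path, sep = "\t", row.names = FALSE, quote = FALSE
  )
  invisible(path)
}
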