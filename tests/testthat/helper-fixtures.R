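# Shared fixtures: everything is generated in code at test time.

# minimal hand-built scale grid for constructing synthetic fields
toy_grid <- function(scales, dt = 1, n = 5, omega0 = 6) {
  ff <- physiowtc::morlet_fourier_factor(omega0)
  structure(
    list(scales = scales, fourier_periods = ff * scales,
         frequencies = 1 / (ff * scales), dj = 1, s0 = scales[1],
         omega0 = omega0, fourier_factor = ff, dt = dt, n = as.integer(n)),
    class = "scale_grid"
  )
}

# hand-built coherence field with full control over r2/phase/cone
toy_coherence <- function(r2, phase, grid, coi_period) {
  structure(
    list(r2 = r2, phase = phase, grid = grid,
         times = (seq_len(ncol(r2)) - 1) * grid$dt, dt = grid$dt,
         coi_period = coi_period, smooth_dj0 = 0.6,
         labels = c(x = "x", y = "y")),
    class = "coherence_field"
  )
}

toy_thresholds <- function(thr, grid) {
  structure(
    list(r2_threshold = thr, grid = grid, alpha = 0.05, n_boot = 0L,
         seed = 0L, model_x = NULL, model_y = NULL, smooth_dj0 = 0.6,
         n_pooled = rep(1L, length(thr))),
    class = "threshold_profile"
  )
}

# direct evaluation of the CWT convolution sum (the independent oracle)
cwt_direct_sum <- function(x, dt, grid) {
  xc <- x - mean(x)
  n <- length(x)
  out <- matrix(0i, length(grid$scales), n)
  for (j in seq_along(grid$scales)) {
    s <- grid$scales[j]
    eta <- outer(seq_len(n), seq_len(n), function(np, nn) (np - nn) * dt / s)
    psi <- Conj(physiowtc::morlet(eta, grid$omega0))
    out[j, ] <- sqrt(dt / s) * as.vector(xc %*% psi)
  }
  out
}
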