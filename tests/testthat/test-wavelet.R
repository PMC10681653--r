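test_that("the Morlet mother wavelet has the analytic value, symmetry and unit energy", {
  expect_equal(morlet(0), pi^(-1 / 4) + 0i)
  eta <- seq(-3, 3, by = 0.37)
  expect_equal(Mod(morlet(eta)), Mod(morlet(-eta)))
  # unit energy by quadrature over [-8, 8]
  energy <- stats::integrate(function(e) Mod(morlet(e))^2, -8, 8,
                             rel.tol = 1e-10)$value
  expect_equal(energy, 1, tolerance = 1e-6)
})

test_that("the scale grid is dyadic with the 1.03 period-scale ratio", {
  grid <- build_scale_grid(0.72, 1200)
  expect_equal(round(morlet_fourier_factor(6), 2), 1.03)
  expect_equal(grid$fourier_periods / grid$scales,
               rep(morlet_fourier_factor(6), length(grid$scales)))
  # dyadic: 1/dj steps double the scale
  v <- round(1 / grid$dj)
  expect_equal(grid$scales[1 + v] / grid$scales[1], 2, tolerance = 1e-12)
  # smallest period ~1.49 s and full coverage of the 0.02-0.4 Hz bands
  expect_equal(grid$fourier_periods[1], 2 * 0.72 * morlet_fourier_factor(6),
               tolerance = 1e-12)
  expect_equal(grid$fourier_periods[1], 1.49, tolerance = 0.01)
  expect_gt(max(grid$frequencies), 0.4)
  expect_lt(min(grid$frequencies), 0.02)
  expect_true(all(diff(grid$frequencies) < 0))
  expect_error(build_scale_grid(0.72, 1200, s0 = 0.1), "s0")
})

test_that("the FFT-based transform equals the direct convolution sum", {
  set.seed(31)
  n <- 128; dt <- 0.72
  x <- rnorm(n)
  grid <- build_scale_grid(dt, n)
  W <- cwt(sampled_series(x, dt), grid)
  direct <- cwt_direct_sum(x, dt, grid)
  expect_lt(max(Mod(W$coeffs - direct)) / max(Mod(direct)), 1e-8)

  # linearity limit: zero input gives zero coefficients
  W0 <- cwt(sampled_series(rep(0, n), dt), grid)
  expect_equal(max(Mod(W0$coeffs)), 0)

  # a 0.1 Hz sinusoid concentrates power at the 10 s period
  n2 <- 1024
  g2 <- build_scale_grid(dt, n2)
  t <- (0:(n2 - 1)) * dt
  Ws <- cwt(sampled_series(sin(2 * pi * 0.1 * t), dt), g2)
  pw <- rowMeans(Mod(Ws$coeffs)^2)
  expect_equal(g2$fourier_periods[which.max(pw)], 10, tolerance = 10 * g2$dj)

  expect_error(cwt(sampled_series(rnorm(64), dt), grid), "match")
})

test_that("the cone of influence vanishes at the edges and inverts correctly", {
  n <- 1200; dt <- 0.72
  coi <- cone_of_influence(n, dt)
  expect_equal(coi[1], 0)
  expect_equal(coi[n], 0)
  expect_equal(coi, rev(coi)) # symmetric about mid-record
  # a 50 s period is trustworthy only where min-edge-distance > 50*sqrt(2)/ff
  tt <- (0:(n - 1)) * dt
  lim <- 50 * sqrt(2) / morlet_fourier_factor(6)
  expect_identical(coi > 50, pmin(tt, tt[n] - tt) > lim)
  expect_equal(lim, 68.45, tolerance = 0.01)
})

test_that("field smoothing is unit-mass, local and linear", {
  n <- 200; dt <- 0.72
  grid <- build_scale_grid(dt, n, max_period = 30)
  # constant field unchanged
  const <- matrix(2.5, length(grid$scales), n)
  expect_equal(smooth_field(const, grid), const, tolerance = 1e-10)
  # unit impulse keeps mass 1 and stays within a few time-kernel sds
  imp <- matrix(0, length(grid$scales), n)
  j0 <- round(length(grid$scales) / 2)
  imp[j0, n / 2] <- 1
  sm <- smooth_field(imp, grid)
  expect_equal(sum(sm), 1, tolerance = 1e-9)
  sd_samp <- grid$scales[j0] / (sqrt(2) * dt)
  far <- abs(seq_len(n) - n / 2) > 4.5 * sd_samp
  expect_lt(max(abs(sm[j0, far])), 1e-6)
  # linearity
  set.seed(5)
  f1 <- matrix(rnorm(length(imp)), nrow(imp))
  expect_equal(smooth_field(3 * f1, grid), 3 * smooth_field(f1, grid),
               tolerance = 1e-12)
})

test_that("cross-wavelet self-product, conjugate symmetry and lagged-sinusoid phase", {
  n <- 512; dt <- 0.72
  grid <- build_scale_grid(dt, n)
  t <- (0:(n - 1)) * dt
  tau <- 2
  x <- sampled_series(sin(2 * pi * 0.1 * t), dt)           # reference
  xd <- sampled_series(sin(2 * pi * 0.1 * (t - tau)), dt)  # delayed copy
  WX <- cwt(x, grid)
  WD <- cwt(xd, grid)

  self <- cross_wavelet(WX, WX)
  expect_equal(self$power, Mod(WX$coeffs)^2, tolerance = 1e-12)
  expect_equal(max(abs(self$phase)), 0, tolerance = 1e-9)

  ab <- cross_wavelet(WX, WD)
  ba <- cross_wavelet(WD, WX)
  expect_equal(ba$coeffs, Conj(ab$coeffs), tolerance = 1e-12)

  # delayed-by-tau series against the original: phase 2 pi f tau at the f scale
  j <- which.min(abs(grid$frequencies - 0.1))
  om <- outer(grid$fourier_periods, WX$coi_period, `<`)
  ph <- Arg(mean(exp(1i * ba$phase[j, om[j, ]])))
  expect_equal(ph, -2 * pi * 0.1 * tau, tolerance = pi / 32)

  g2 <- build_scale_grid(dt, 128)
  expect_error(cross_wavelet(WX, cwt(sampled_series(rnorm(128), dt), g2)),
               "grid")
})

test_that("coherence is exactly 1 for self-pairs and degenerate without smoothing", {
  n <- 300; dt <- 0.72
  grid <- build_scale_grid(dt, n)
  x <- gen_ar1_series(0.5, 1, n, dt, seed = 61)
  co <- wtc(x, x, grid)
  pre <- attr(co, "preclip_range")
  expect_lt(max(abs(pre - 1)), 1e-9)
  expect_true(all(co$r2 >= 0 & co$r2 <= 1))

  # regression guard: the unsmoothed ratio is identically 1 even for
  # independent inputs, so any non-degenerate output proves smoothing ran
  y <- gen_ar1_series(0.5, 1, n, dt, seed = 62)
  WX <- cwt(x, grid)$coeffs
  WY <- cwt(y, grid)$coeffs
  raw <- Mod(WX * Conj(WY))^2 / (Mod(WX)^2 * Mod(WY)^2)
  expect_lt(max(abs(raw - 1)), 1e-9)
  co_xy <- wtc(x, y, grid)
  om <- out_of_cone(co_xy)
  expect_lt(mean(co_xy$r2[om]), 0.8)

  expect_error(wtc(sampled_series(rep(1, n), dt), x, grid), "degenerate")
})

test_that("imposed lags are recovered as phases at the coupling scale", {
  pr <- gen_coupled_pair(coupling_scenario(n_frames = 1200, coupling_freq = 0.1,
                                           coupling_strength = 5,
                                           phase_lag = pi / 2, seed = 63))
  grid <- build_scale_grid(0.72, 1200)
  co <- wtc(pr$physio, pr$bold, grid)
  j <- which.min(abs(grid$frequencies - 0.1))
  om <- out_of_cone(co)
  ph <- Arg(mean(exp(1i * co$phase[j, om[j, ]])))
  # physio trails BOLD by a quarter period: phase -pi/2 by the convention
  expect_equal(ph, -pi / 2, tolerance = pi / 16)
})

test_that("coherence fields export as text matrices with a JSON sidecar", {
  n <- 128; dt <- 0.72
  grid <- build_scale_grid(dt, n)
  co <- wtc(gen_ar1_series(0.5, 1, n, dt, seed = 71),
            gen_ar1_series(0.5, 1, n, dt, seed = 72), grid)
  stem <- file.path(tempdir(), "field")
  write_coherence_field(co, stem)
  r2 <- as.matrix(utils::read.table(paste0(stem, "_r2.tsv"), sep = "\t"))
  expect_equal(unname(r2), unname(co$r2), tolerance = 1e-12)
  ax <- jsonlite::read_json(paste0(stem, "_axes.json"), simplifyVector = TRUE)
  expect_equal(ax$scales_s, grid$scales)
  file.remove(list.files(tempdir(), "^field_", full.names = TRUE))
})
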