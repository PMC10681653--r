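test_that("AR(1) generator has white-noise, stationary-variance and noise-free limits", {
  # white noise: lag-1 autocorrelation near zero
  x <- gen_ar1_series(0, 1, 1000, dt = 1, seed = 1)
  r1 <- stats::acf(x$values, lag.max = 1, plot = FALSE)$acf[2]
  expect_lt(abs(r1), 0.1)

  # stationary variance sigma^2 / (1 - phi^2)
  y <- gen_ar1_series(0.8, 1, 5000, dt = 1, seed = 2)
  expect_lt(abs(stats::var(y$values) - 1 / (1 - 0.8^2)) / (1 / (1 - 0.8^2)), 0.15)

  # noise-free recursion from a forced start is a geometric decay
  z <- gen_ar1_series(0.5, 0, 10, dt = 1, seed = 3, x0 = 1)
  expect_equal(z$values, 0.5^(0:9))

  # reproducibility and error paths
  expect_identical(gen_ar1_series(0.3, 1, 50, seed = 7)$values,
                   gen_ar1_series(0.3, 1, 50, seed = 7)$values)
  expect_error(gen_ar1_series(1, 1, 100), "stationary")
  expect_error(gen_ar1_series(0.5, 1, 1), "at least 2")
})

test_that("pulse generator lays down recoverable beats at the requested intervals", {
  prof <- sampled_series(rep(1, 61), dt = 1)
  rec <- gen_pulse_recording(prof, physio_rate = 400, seed = 1)
  pk <- detect_pulse_peaks(rec)
  expect_true(length(pk) %in% c(59, 60))
  expect_lt(max(abs(diff(pk$times) - 1)), 0.0025 + 1e-12)

  # sinusoidally modulated intervals: recovered interval series peaks at 0.1 Hz
  t2 <- seq(0, 120, by = 0.5)
  prof2 <- sampled_series(1 + 0.1 * sin(2 * pi * 0.1 * t2), dt = 0.5)
  pk2 <- detect_pulse_peaks(gen_pulse_recording(prof2, physio_rate = 200, seed = 3))
  iv <- diff(pk2$times)
  mids <- pk2$times[-length(pk2$times)] + iv / 2
  ivu <- stats::approx(mids, iv, xout = seq(1, 119, by = 0.5), rule = 2)$y
  sp <- stats::spec.pgram(stats::ts(ivu - mean(ivu), deltat = 0.5),
                          plot = FALSE, taper = 0)
  expect_equal(sp$freq[which.max(sp$spec)], 0.1, tolerance = 0.02)

  expect_error(gen_pulse_recording(sampled_series(numeric(0), dt = 1)))
  expect_error(gen_pulse_recording(sampled_series(rep(3, 10), dt = 1)), "range")
})

test_that("respiration generator encodes the requested RVT profile", {
  # constant profile recovered within 5%
  rprof <- sampled_series(rep(0.5, 121), dt = 1)
  rr <- gen_respiration_recording(rprof, physio_rate = 100, seed = 2)
  ex <- detect_breath_extrema(rr)
  rvt <- compute_rvt(ex$maxima, ex$minima, seq(5, 115, by = 0.72))
  expect_lt(max(abs(rvt$values - 0.5)) / 0.5, 0.05)

  # a step at t = 150 s shows up in the recovered series
  t <- seq(0, 300, by = 1)
  sprof <- sampled_series(ifelse(t < 150, 0.4, 0.8), dt = 1)
  rs <- gen_respiration_recording(sprof, physio_rate = 100, seed = 3)
  exs <- detect_breath_extrema(rs)
  rvs <- compute_rvt(exs$maxima, exs$minima, seq(5, 295, by = 0.72))
  tt <- series_times(rvs)
  expect_gt(mean(rvs$values[tt > 160]) - mean(rvs$values[tt < 140]), 0.3)

  expect_error(gen_respiration_recording(sampled_series(c(0.5, -0.1), dt = 1)),
               "positive")
  expect_error(gen_respiration_recording(rprof, physio_rate = 0.4), "aliasing")
})

test_that("coupled pairs carry the designed coherence, phase and independence structure", {
  n <- 600; dt <- 0.72
  grid <- build_scale_grid(dt, n)
  j <- which.min(abs(grid$frequencies - 0.1))

  # strong coupling, zero lag: R2 near 1 and phase near 0 at the coupling scale
  p1 <- gen_coupled_pair(coupling_scenario(n_frames = n, coupling_freq = 0.1,
                                           coupling_strength = 5, seed = 4))
  co <- wtc(p1$physio, p1$bold, grid)
  om <- out_of_cone(co)
  expect_gt(mean(co$r2[j, om[j, ]]), 0.9)
  expect_lt(abs(Arg(mean(exp(1i * co$phase[j, om[j, ]])))), pi / 16)

  # no coupling: series uncorrelated, coherence far from 1
  p0 <- gen_coupled_pair(coupling_scenario(n_frames = n, coupling_freq = 0.1,
                                           coupling_strength = 0, seed = 5))
  expect_lt(abs(stats::cor(p0$bold$values, p0$physio$values)), 0.15)
  co0 <- wtc(p0$physio, p0$bold, grid)
  expect_lt(mean(co0$r2[j, om[j, ]]), 0.5)

  # quarter-period lag at 0.1 Hz: physio trails BOLD by 2.5 s
  pl <- gen_coupled_pair(coupling_scenario(n_frames = 1200, coupling_freq = 0.1,
                                           coupling_strength = 5,
                                           phase_lag = pi / 2, seed = 6))
  lag <- xcorr_peak_lag(pl$physio, pl$bold, band_spec("b", 0.05, 0.15), max_lag = 4)
  expect_lt(abs(lag - 2.5), 0.72 + 1e-9)

  expect_error(coupling_scenario(coupling_freq = 2), "coupling_freq")
})

test_that("frequency and phase lag are recovered across seeds at high SNR", {
  n <- 600; dt <- 0.72
  grid <- build_scale_grid(dt, n)
  hits_f <- hits_p <- 0
  nseed <- 10
  for (r in seq_len(nseed)) {
    pr <- gen_coupled_pair(coupling_scenario(n_frames = n, coupling_freq = 0.1,
                                             coupling_strength = 5,
                                             phase_lag = pi / 4, seed = 40 + r))
    co <- wtc(pr$physio, pr$bold, grid)
    om <- out_of_cone(co)
    mr2 <- vapply(seq_along(grid$scales), function(j) mean(co$r2[j, om[j, ]]),
                  numeric(1))
    jbest <- which.max(ifelse(is.nan(mr2), -1, mr2))
    # localisation up to half the scale-smoothing span (0.3 octave)
    if (abs(log2(grid$frequencies[jbest] / 0.1)) <= 0.3 + 1e-9) hits_f <- hits_f + 1
    jc <- which.min(abs(grid$frequencies - 0.1))
    ph <- Arg(mean(exp(1i * co$phase[jc, om[jc, ]])))
    if (abs(ph - (-pi / 4)) <= pi / 8) hits_p <- hits_p + 1
  }
  expect_gte(hits_f, ceiling(0.95 * nseed))
  expect_gte(hits_p, ceiling(0.95 * nseed))
})

test_that("synthetic studies are reproducible and round-trip through the readers", {
  scn <- coupling_scenario(n_frames = 96, dt_frames = 0.72, physio_rate = 100,
                           coupling_freq = 0.1, coupling_strength = 2, seed = 1)
  d1 <- file.path(tempdir(), "study_a")
  d2 <- file.path(tempdir(), "study_b")
  gen_study(2, scn, seed = 5, dir = d1)
  gen_study(2, scn, seed = 5, dir = d2)
  for (f in list.files(d1)) {
    expect_identical(unname(tools::md5sum(file.path(d1, f))),
                     unname(tools::md5sum(file.path(d2, f))), label = f)
  }
  man <- jsonlite::read_json(file.path(d1, "manifest.json"), simplifyVector = TRUE)
  expect_length(man$subjects, 2)
  rec <- read_physio_recording(file.path(d1, "sub01_pulse.tsv"))
  expect_s3_class(rec, "sampled_series")
  expect_equal(rec$dt, 1 / 100, tolerance = 1e-6)
  bold <- read_bold_table(file.path(d1, "sub01_bold.tsv"), dt = 0.72)
  expect_named(bold, c("DAN", "DMN", "FPN", "LN", "SMN", "VAN", "VN"))
  expect_length(bold$DAN$values, 96)
  expect_error(gen_study(1, scn), "at least 2")
  unlink(c(d1, d2), recursive = TRUE)
})
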