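#' Ground-truth coupling scenario for synthetic recordings
#'
#' Bundles every knob of the synthetic study: record geometry (frames at the
#' scanner's frame spacing, raw physiology at the peripheral sampling rate),
#' AR(1) backgrounds, and a shared band-limited oscillation injected into both
#' the BOLD-like and physiology-like series at a configurable frequency,
#' strength, phase lag and set of on-epochs. Defaults emulate a 15-minute
#' fast-TR resting-state scan: 1200 frames at 0.72 s with 400 Hz peripheral
#' recordings.
#'
#' @param n_frames Number of imaging frames (>= 64).
#' @param dt_frames Frame spacing in seconds.
#' @param physio_rate Peripheral sampling rate in Hz.
#' @param coupling_freq Shared-oscillation frequency in Hz (must be below the
#'   frame-rate Nyquist).
#' @param coupling_strength Oscillation amplitude as a multiple of the AR
#'   background's stationary standard deviation (0 = no coupling).
#' @param phase_lag Phase of the physiological copy relative to BOLD, in
#'   radians; positive means the physiological series is delayed (trails) by
#'   `phase_lag / (2 pi coupling_freq)` seconds.
#' @param coupling_epochs List of `c(start, end)` second pairs during which
#'   the coupling is on; `NULL` means the whole record.
#' @param ar_coeff_bold,ar_coeff_physio AR(1) coefficients in (-1, 1).
#' @param noise_sd Innovation standard deviation of the AR backgrounds.
#' @param seed Integer seed making every derived draw reproducible.
#' @return An object of class `coupling_scenario`.
#' @export
coupling_scenario <- function(n_frames = 1200, dt_frames = 0.72,
                              physio_rate = 400, coupling_freq = 0.1,
                              coupling_strength = 1, phase_lag = 0,
                              coupling_epochs = NULL,
                              ar_coeff_bold = 0.5, ar_coeff_physio = 0.5,
                              noise_sd = 1, seed = 1L) {
  if (n_frames < 64) stop("`n_frames` must be at least 64", call. = FALSE)
  nyq <- 1 / (2 * dt_frames)
  if (coupling_freq <= 0 || coupling_freq >= nyq) {
    stop(sprintf("`coupling_freq` must lie in (0, %.3f) Hz", nyq), call. = FALSE)
  }
  if (abs(ar_coeff_bold) >= 1 || abs(ar_coeff_physio) >= 1) {
    stop("AR coefficients must have modulus < 1", call. = FALSE)
  }
  if (coupling_strength < 0) stop("`coupling_strength` must be >= 0", call. = FALSE)
  span <- n_frames * dt_frames
  if (is.null(coupling_epochs)) coupling_epochs <- list(c(0, span))
  for (ep in coupling_epochs) {
    if (length(ep) != 2 || ep[1] >= ep[2] || ep[1] < 0 || ep[2] > span + 1e-9) {
      stop("each coupling epoch must be c(start, end) within the record", call. = FALSE)
    }
  }
  structure(
    list(n_frames = as.integer(n_frames), dt_frames = dt_frames,
         physio_rate = physio_rate, coupling_freq = coupling_freq,
         coupling_strength = coupling_strength, phase_lag = phase_lag,
         coupling_epochs = coupling_epochs, ar_coeff_bold = ar_coeff_bold,
         ar_coeff_physio = ar_coeff_physio, noise_sd = noise_sd,
         seed = as.integer(seed)),
    class = "coupling_scenario"
  )
}

#' Simulate a stationary AR(1) series
#'
#' `x[t] = phi * x[t-1] + eps[t]`, `eps ~ N(0, sigma^2)`, started from the
#' stationary distribution (or a forced initial value).
#'
#' @param phi AR(1) coefficient, |phi| < 1.
#' @param sigma Innovation standard deviation (>= 0).
#' @param n Length (>= 2).
#' @param dt Sampling step in seconds.
#' @param seed Integer seed (NULL = current RNG stream).
#' @param x0 Optional forced initial value; by default drawn from
#'   N(0, sigma^2 / (1 - phi^2)).
#' @return A [sampled_series()].
#' @export
gen_ar1_series <- function(phi, sigma, n, dt = 1, seed = NULL, x0 = NULL) {
  if (abs(phi) >= 1) stop("non-stationary: |phi| must be < 1", call. = FALSE)
  if (n < 2) stop("`n` must be at least 2", call. = FALSE)
  stopifnot(sigma >= 0)
  vals <- with_seed_if(seed, {
    start <- if (is.null(x0)) stats::rnorm(1, 0, sigma / sqrt(1 - phi^2)) else x0
    eps <- stats::rnorm(n - 1, 0, sigma)
    c(start, as.numeric(stats::filter(eps, phi, method = "recursive", init = start)))
  })
  sampled_series(vals, dt = dt, label = sprintf("ar1(phi=%g)", phi))
}

# interpolate a profile series at arbitrary times, holding boundary values
profile_at <- function(profile, t) {
  stats::approx(series_times(profile), profile$values, xout = t, rule = 2)$y
}

#' Synthesize a pulse-oximeter-like recording
#'
#' Lays down a raised-cosine pulse train whose successive systolic peak
#' spacings follow `beat_interval_profile` (a slowly varying series of
#' beat-to-beat intervals in seconds), sampled at `physio_rate`. Pulse
#' morphology is deliberately minimal: only the peak times carry information.
#'
#' @param beat_interval_profile [sampled_series()] of beat intervals (s),
#'   all within the physiological range \[0.3, 2\] s.
#' @param physio_rate Output sampling rate in Hz.
#' @param seed Seed for the small additive sensor noise.
#' @param noise_sd Standard deviation of the additive noise (signal units;
#'   pulse peak height is 1).
#' @return A [sampled_series()] at `1/physio_rate` resolution spanning the
#'   profile's time range.
#' @export
gen_pulse_recording <- function(beat_interval_profile, physio_rate = 400,
                                seed = NULL, noise_sd = 0.002) {
  stopifnot(inherits(beat_interval_profile, "sampled_series"))
  if (!length(beat_interval_profile$values)) {
    stop("empty beat-interval profile", call. = FALSE)
  }
  if (any(beat_interval_profile$values < 0.3 | beat_interval_profile$values > 2)) {
    stop("beat intervals outside the physiological range [0.3, 2] s", call. = FALSE)
  }
  t_end <- max(series_times(beat_interval_profile))
  t0 <- beat_interval_profile$t0
  # place peaks sequentially: next peak one local interval after the last
  peaks <- numeric(0)
  tcur <- t0 + profile_at(beat_interval_profile, t0) / 2
  while (tcur <= t_end) {
    peaks <- c(peaks, tcur)
    tcur <- tcur + profile_at(beat_interval_profile, tcur)
  }
  dt <- 1 / physio_rate
  tt <- seq(t0, t_end, by = dt)
  v <- numeric(length(tt))
  width <- 0.12 # half-width (s) of the raised-cosine pulse
  for (p in peaks) {
    idx <- which(tt >= p - width & tt <= p + width)
    v[idx] <- v[idx] + 0.5 * (1 + cos(pi * (tt[idx] - p) / width))
  }
  v <- v + with_seed_if(seed, stats::rnorm(length(v), 0, noise_sd))
  out <- sampled_series(v, dt = dt, t0 = t0, label = "pulse")
  attr(out, "truth_peak_times") <- peaks
  out
}

#' Synthesize a respiratory-bellows-like recording
#'
#' A breath oscillation at a fixed base rate (0.25 Hz) whose amplitude is
#' modulated so that the per-breath (peak - trough) / breath-period ratio
#' tracks `rvt_profile`. Extrema are recoverable by
#' [detect_breath_extrema()].
#'
#' @param rvt_profile Strictly positive [sampled_series()] of target
#'   respiration-volume-per-time values.
#' @param physio_rate Output sampling rate (Hz); must exceed twice the breath
#'   rate.
#' @param seed Seed for the small additive sensor noise.
#' @param breath_rate Base breathing rate in Hz (default 0.25).
#' @param noise_sd Additive noise standard deviation.
#' @return A [sampled_series()].
#' @export
gen_respiration_recording <- function(rvt_profile, physio_rate = 400,
                                      seed = NULL, breath_rate = 0.25,
                                      noise_sd = 0.01) {
  stopifnot(inherits(rvt_profile, "sampled_series"))
  if (any(rvt_profile$values <= 0)) {
    stop("`rvt_profile` must be strictly positive", call. = FALSE)
  }
  if (physio_rate <= 2 * breath_rate) {
    stop("`physio_rate` below twice the breathing rate: aliasing", call. = FALSE)
  }
  dt <- 1 / physio_rate
  t0 <- rvt_profile$t0
  tt <- seq(t0, max(series_times(rvt_profile)), by = dt)
  # (max - min)/period = rvt with a symmetric oscillation of amplitude a:
  # 2 a * breath_rate = rvt  =>  a = rvt / (2 * breath_rate)
  amp <- profile_at(rvt_profile, tt) / (2 * breath_rate)
  v <- amp * sin(2 * pi * breath_rate * (tt - t0))
  v <- v + with_seed_if(seed, stats::rnorm(length(v), 0, noise_sd))
  sampled_series(v, dt = dt, t0 = t0, label = "respiration")
}

# epoch indicator over frame times
epoch_gate <- function(times, epochs) {
  on <- rep(FALSE, length(times))
  for (ep in epochs) on <- on | (times >= ep[1] & times <= ep[2])
  on
}

#' Generate a coupled BOLD-like / physiology-like pair at the frame rate
#'
#' Two independent AR(1) backgrounds plus, inside the coupling epochs, a
#' shared sinusoid at `coupling_freq` with amplitude
#' `coupling_strength * sd_background`; the physiological copy is delayed by
#' `phase_lag / (2 pi coupling_freq)` seconds (it trails BOLD for positive
#' lags).
#'
#' @param scn A [coupling_scenario()].
#' @return List with [sampled_series()] elements `bold` and `physio` and a
#'   `truth` list recording frequency, lag, epochs and amplitude.
#' @export
gen_coupled_pair <- function(scn) {
  stopifnot(inherits(scn, "coupling_scenario"))
  n <- scn$n_frames
  dt <- scn$dt_frames
  tt <- (seq_len(n) - 1) * dt
  sd_bg <- scn$noise_sd / sqrt(1 - max(abs(scn$ar_coeff_bold), abs(scn$ar_coeff_physio))^2)
  amp <- scn$coupling_strength * sd_bg
  lag_s <- scn$phase_lag / (2 * pi * scn$coupling_freq)
  gate <- epoch_gate(tt, scn$coupling_epochs)
  out <- with_seed_if(scn$seed, {
    b <- gen_ar1_series(scn$ar_coeff_bold, scn$noise_sd, n, dt)
    p <- gen_ar1_series(scn$ar_coeff_physio, scn$noise_sd, n, dt)
    list(b = b, p = p)
  })
  bold <- out$b$values + amp * gate * sin(2 * pi * scn$coupling_freq * tt)
  physio <- out$p$values + amp * gate * sin(2 * pi * scn$coupling_freq * (tt - lag_s))
  list(
    bold = sampled_series(bold, dt = dt, label = "bold"),
    physio = sampled_series(physio, dt = dt, label = "physio"),
    truth = list(coupling_freq = scn$coupling_freq, phase_lag = scn$phase_lag,
                 lag_seconds = lag_s, epochs = scn$coupling_epochs,
                 amplitude = amp)
  )
}

#' Generate a synthetic multi-subject study on disk
#'
#' Writes, for each subject, raw pulse and respiration recordings (two-column
#' tab-separated text at `physio_rate`), a frames x 7 network BOLD table, and
#' one JSON manifest holding the per-subject ground truth. Coupling between
#' the physiological signals and the selected networks is injected through
#' the beat-interval profile (heart-rate modulation at `coupling_freq`) and
#' the respiration-depth profile, with matching band-limited oscillations
#' added to the coupled networks' BOLD series.
#'
#' @param n_subjects Number of subjects (>= 2).
#' @param scn_template A [coupling_scenario()] giving the shared defaults.
#' @param coupled_networks Character vector of network labels receiving the
#'   coupling (subset of the seven canonical labels).
#' @param between_subject_jitter Relative jitter (sd, as a fraction) applied
#'   to each subject's coupling strength and AR coefficients.
#' @param seed Integer master seed; per-subject seeds are derived by a fixed
#'   offset of 1000 per subject.
#' @param dir Output directory (created if missing).
#' @param hbi_mod Fractional heart-rate modulation depth at the coupling
#'   frequency (default 0.05, i.e. 5 percent of the mean beat interval).
#' @param rvt_freq,rvt_mod Frequency (Hz) and fractional depth of the
#'   respiration-depth modulation shared with the coupled networks.
#' @return Invisibly, the manifest path.
#' @export
gen_study <- function(n_subjects, scn_template = coupling_scenario(),
                      coupled_networks = c("SMN", "VAN", "VN"),
                      between_subject_jitter = 0.1, seed = 1L,
                      dir = tempfile("physiowtc_study_"),
                      hbi_mod = 0.05, rvt_freq = 0.03, rvt_mod = 0.3) {
  if (n_subjects < 2) stop("`n_subjects` must be at least 2", call. = FALSE)
  nets <- c("DAN", "DMN", "FPN", "LN", "SMN", "VAN", "VN")
  stopifnot(all(coupled_networks %in% nets))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  scn <- scn_template
  n <- scn$n_frames
  dt <- scn$dt_frames
  frame_t <- (seq_len(n) - 1) * dt
  span <- n * dt
  manifest <- list(
    networks = nets, coupled_networks = coupled_networks,
    n_frames = n, dt_frames = dt, physio_rate = scn$physio_rate,
    seed = seed, subjects = list()
  )
  for (i in seq_len(n_subjects)) {
    sid <- sprintf("sub%02d", i)
    sseed <- as.integer(seed + 1000L * i)
    pars <- with_seed_if(sseed, list(
      strength = max(0, scn$coupling_strength *
                       (1 + stats::rnorm(1, 0, between_subject_jitter))),
      ar_bold = pmin(0.95, pmax(-0.95, scn$ar_coeff_bold *
                                  (1 + stats::rnorm(1, 0, between_subject_jitter)))),
      ar_physio = pmin(0.95, pmax(-0.95, scn$ar_coeff_physio *
                                    (1 + stats::rnorm(1, 0, between_subject_jitter))))
    ))
    gate <- epoch_gate(frame_t, scn$coupling_epochs)
    lag_s <- scn$phase_lag / (2 * pi * scn$coupling_freq)

    # cardiac: beat intervals around 1 s; the HBI (rate) series then carries
    # +hbi_mod * sin(2 pi f (t - lag)) to first order
    prof_t <- seq(0, span, by = dt)
    gate_p <- epoch_gate(prof_t, scn$coupling_epochs)
    ivals <- 1 / (1 + hbi_mod * gate_p *
                    sin(2 * pi * scn$coupling_freq * (prof_t - lag_s)))
    pulse <- gen_pulse_recording(
      sampled_series(ivals, dt = dt, label = "beat intervals"),
      physio_rate = scn$physio_rate, seed = sseed + 1L
    )

    # respiratory: depth modulation at rvt_freq shared with coupled networks
    rvt_truth <- 0.5 * (1 + rvt_mod * gate_p *
                          sin(2 * pi * rvt_freq * (prof_t - lag_s)))
    resp <- gen_respiration_recording(
      sampled_series(rvt_truth, dt = dt, label = "rvt profile"),
      physio_rate = scn$physio_rate, seed = sseed + 2L
    )

    # BOLD: AR(1) background per network; coupled networks additionally get
    # the oscillations shared with HBI (at coupling_freq) and RVT (rvt_freq)
    bold <- with_seed_if(sseed + 3L, {
      m <- sapply(seq_along(nets), function(k) {
        gen_ar1_series(pars$ar_bold, scn$noise_sd, n, dt)$values
      })
      colnames(m) <- nets
      m
    })
    sd_bg <- scn$noise_sd / sqrt(1 - pars$ar_bold^2)
    osc <- pars$strength * sd_bg * gate *
      (sin(2 * pi * scn$coupling_freq * frame_t) +
         sin(2 * pi * rvt_freq * frame_t))
    for (netname in coupled_networks) {
      bold[, netname] <- bold[, netname] + osc
    }

    write_physio_recording(pulse, file.path(dir, paste0(sid, "_pulse.tsv")))
    write_physio_recording(resp, file.path(dir, paste0(sid, "_resp.tsv")))
    utils::write.table(bold, file.path(dir, paste0(sid, "_bold.tsv")),
                       sep = "\t", row.names = FALSE, quote = FALSE)
    manifest$subjects[[sid]] <- list(
      id = sid, seed = sseed, coupling_strength = pars$strength,
      ar_coeff_bold = pars$ar_bold, ar_coeff_physio = pars$ar_physio,
      coupling_freq = scn$coupling_freq, rvt_freq = rvt_freq,
      phase_lag = scn$phase_lag, hbi_mod = hbi_mod, rvt_mod = rvt_mod,
      epochs = scn$coupling_epochs
    )
  }
  manifest_path <- file.path(dir, "manifest.json")
  jsonlite::write_json(manifest, manifest_path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(manifest_path)
}
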