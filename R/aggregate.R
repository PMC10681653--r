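#' Frequency band specification
#'
#' @param name Band label.
#' @param f_lo,f_hi Band edges in Hz (0 < f_lo < f_hi).
#' @return An object of class `band_spec`.
#' @export
band_spec <- function(name, f_lo, f_hi) {
  if (!(f_lo > 0 && f_lo < f_hi)) stop("need 0 < f_lo < f_hi", call. = FALSE)
  structure(list(name = name, f_lo = f_lo, f_hi = f_hi), class = "band_spec")
}

#' Default analysis bands
#'
#' The two heartbeat-interval bands (low 0.05-0.15 Hz, driven by mixed
#' sympathetic/parasympathetic outflow; high 0.15-0.4 Hz, respiration-coupled)
#' and the dominant respiration-volume-per-time band (0.02-0.04 Hz).
#'
#' @return Named list of [band_spec()] objects.
#' @export
default_bands <- function() {
  list(
    hbi_low = band_spec("HBI-low", 0.05, 0.15),
    hbi_high = band_spec("HBI-high", 0.15, 0.4),
    rvt = band_spec("RVT", 0.02, 0.04)
  )
}

#' Phase-offset bins
#'
#' Four half-open quarter-circle arcs centred at 0 (in-phase), pi/2
#' (physiology leading), pi (anti-phase) and -pi/2 (BOLD leading), each of
#' half-width pi/4: `[centre - pi/4, centre + pi/4)`. The arcs partition the
#' circle exactly, so every phase falls in exactly one bin.
#'
#' @return An object of class `phase_bins` with `centers` and `labels`.
#' @export
phase_bins <- function() {
  structure(
    list(centers = c(0, pi / 2, pi, -pi / 2),
         labels = c("inphase", "physio_leads", "antiphase", "bold_leads")),
    class = "phase_bins"
  )
}

# bin index (1..4) of each phase in (-pi, pi]
phase_bin_index <- function(phi, bins = phase_bins()) {
  if (any(phi > pi + 1e-12 | phi <= -pi - 1e-12)) {
    stop("phase outside (-pi, pi]", call. = FALSE)
  }
  # rotate so bin k covers [(k-1) - 1/2, (k-1) + 1/2) quarter turns
  q <- floor(phi / (pi / 2) + 0.5) %% 4
  as.integer(q) + 1L
}

#' Significance mask of a coherence field
#'
#' TRUE where R-squared exceeds the per-scale Monte-Carlo threshold and the
#' point lies outside the cone of influence. Scales without a threshold
#' (inside-cone everywhere) are FALSE.
#'
#' @param coh A [wtc()] coherence field.
#' @param thr A [bootstrap_thresholds()] profile on the same grid.
#' @return Logical matrix (scales x time).
#' @export
significance_mask <- function(coh, thr) {
  stopifnot(inherits(coh, "coherence_field"), inherits(thr, "threshold_profile"))
  if (!isTRUE(all.equal(coh$grid$scales, thr$grid$scales))) {
    stop("coherence field and thresholds are on different scale grids", call. = FALSE)
  }
  t_ok <- ifelse(is.na(thr$r2_threshold), Inf, thr$r2_threshold)
  (coh$r2 > t_ok) & out_of_cone(coh)
}

#' Percent time with significant coherence, per frequency and per band
#'
#' Per frequency: 100 x (significant out-of-cone points) / (all out-of-cone
#' points at that frequency). Per band: the mean of the per-frequency
#' percentages over grid frequencies inside the band (so coarse and fine
#' grids weight frequencies equally); set `band_mode = "pooled"` to pool raw
#' point counts across the band instead.
#'
#' @param mask Logical matrix from [significance_mask()] (cone applied).
#' @param coh The coherence field the mask came from.
#' @param bands List of [band_spec()]; default [default_bands()].
#' @param band_mode `"mean"` (default) or `"pooled"`.
#' @return An object of class `band_profile`: data frame `per_frequency`
#'   (frequency_hz, pct_sig, n_points) and data frame `per_band`
#'   (band, f_lo, f_hi, pct_sig).
#' @export
percent_time_significant <- function(mask, coh, bands = default_bands(),
                                     band_mode = c("mean", "pooled")) {
  band_mode <- match.arg(band_mode)
  stopifnot(inherits(coh, "coherence_field"))
  om <- out_of_cone(coh)
  n_oc <- rowSums(om)
  n_sig <- rowSums(mask & om)
  pct <- ifelse(n_oc > 0, 100 * n_sig / n_oc, NA_real_)
  freqs <- coh$grid$frequencies
  per_band <- do.call(rbind, lapply(bands, function(b) {
    sel <- freqs >= b$f_lo & freqs <= b$f_hi & n_oc > 0
    if (!any(sel)) stop(sprintf("band %s contains no grid frequency", b$name), call. = FALSE)
    p <- if (band_mode == "mean") mean(pct[sel]) else
      100 * sum(n_sig[sel]) / sum(n_oc[sel])
    data.frame(band = b$name, f_lo = b$f_lo, f_hi = b$f_hi, pct_sig = p)
  }))
  rownames(per_band) <- NULL
  structure(
    list(
      per_frequency = data.frame(frequency_hz = freqs, pct_sig = pct,
                                 n_points = n_oc),
      per_band = per_band, band_mode = band_mode
    ),
    class = "band_profile"
  )
}

#' @export
print.band_profile <- function(x, ...) {
  cat("<band_profile>\n")
  print(x$per_band, row.names = FALSE)
  invisible(x)
}

#' Split percent time significant by phase-offset category
#'
#' Each significant out-of-cone point is assigned to exactly one of the four
#' phase bins by the coherence field's phase (taken from the same smoothed
#' cross-spectrum estimator as R-squared). With the package's convention
#' (physiological signal as signal of interest, BOLD as reference), +pi/2
#' means the physiological signal leads BOLD by a quarter cycle and -pi/2
#' that BOLD leads. The per-bin percentages sum to the unsplit percentage at
#' every frequency.
#'
#' @param coh A [wtc()] coherence field.
#' @param mask Logical significance mask from [significance_mask()].
#' @param bins [phase_bins()] (the canonical four-quadrant partition).
#' @return A data frame per frequency: `frequency_hz`, `pct_sig`, one
#'   `pct_<label>` column per bin, `n_points`.
#' @export
categorize_phase <- function(coh, mask, bins = phase_bins()) {
  stopifnot(inherits(coh, "coherence_field"))
  om <- out_of_cone(coh)
  n_oc <- rowSums(om)
  ns <- nrow(coh$r2)
  counts <- matrix(0, ns, 4)
  for (j in seq_len(ns)) {
    sel <- mask[j, ] & om[j, ]
    if (any(sel)) {
      idx <- phase_bin_index(coh$phase[j, sel], bins)
      counts[j, ] <- tabulate(idx, 4)
    }
  }
  pct <- 100 * counts / ifelse(n_oc > 0, n_oc, NA_real_)
  out <- data.frame(frequency_hz = coh$grid$frequencies,
                    pct_sig = rowSums(pct))
  for (k in seq_along(bins$labels)) out[[paste0("pct_", bins$labels[k])]] <- pct[, k]
  out$n_points <- n_oc
  out
}

#' Band-limited peak cross-correlation lag
#'
#' Band-passes both series (zero-phase Butterworth of order `order`, applied
#' forward-backward), computes the normalized cross-correlation over lags up
#' to `max_lag`, and returns the lag of the maximum. Positive lag means the
#' physiological series `x` trails the BOLD series `y`.
#'
#' @param x Physiological [sampled_series()].
#' @param y BOLD [sampled_series()] (equal length and dt).
#' @param band A [band_spec()] below the Nyquist frequency.
#' @param max_lag Largest lag searched, in seconds (< half the record).
#' @param order Butterworth order of the band-pass (default 4).
#' @return Lag in seconds at the cross-correlation peak.
#' @export
xcorr_peak_lag <- function(x, y, band, max_lag = 20, order = 4) {
  stopifnot(inherits(x, "sampled_series"), inherits(y, "sampled_series"),
            inherits(band, "band_spec"))
  if (length(x$values) != length(y$values) || abs(x$dt - y$dt) > 1e-12) {
    stop("`x` and `y` must share length and dt", call. = FALSE)
  }
  n <- length(x$values)
  ny <- 1 / (2 * x$dt)
  if (band$f_hi >= ny) stop("band extends beyond the Nyquist frequency", call. = FALSE)
  if (max_lag >= n * x$dt / 2) stop("`max_lag` must be below half the record", call. = FALSE)
  bf <- signal::butter(order, c(band$f_lo, band$f_hi) / ny, type = "pass")
  xf <- signal::filtfilt(bf, x$values - mean(x$values))
  yf <- signal::filtfilt(bf, y$values - mean(y$values))
  lag_max <- floor(max_lag / x$dt)
  cc <- stats::ccf(xf, yf, lag.max = lag_max, plot = FALSE, demean = TRUE)
  cc$lag[which.max(cc$acf)] * x$dt
}

#' Write a phase-split band profile as text
#'
#' Tab-separated per-frequency rows
#' `(frequency_hz, pct_sig, pct_inphase, pct_physio_leads, pct_antiphase,
#' pct_bold_leads, n_points)` followed by per-band summary rows.
#'
#' @param phase_tbl Data frame from [categorize_phase()].
#' @param profile A [percent_time_significant()] profile for the band rows.
#' @param path Output path.
#' @export
write_band_profile <- function(phase_tbl, profile, path) {
  utils::write.table(phase_tbl, path, sep = "\t", row.names = FALSE, quote = FALSE)
  bandpath <- sub("(\\.[^.]*)?$", "_bands\\1", path)
  utils::write.table(profile$per_band, bandpath, sep = "\t",
                     row.names = FALSE, quote = FALSE)
  invisible(path)
}
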