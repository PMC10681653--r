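#' Run the full coherence pipeline over a synthetic or on-disk study
#'
#' For every subject: detects pulse peaks and breath extrema in the raw
#' recordings, derives frame-aligned heartbeat-interval (HBI) and
#' respiration-volume-per-time (RVT) series, mean-normalizes everything,
#' then for each (physiological signal, network) pair fits the AR null
#' models, builds per-scale Monte-Carlo thresholds, computes wavelet
#' coherence, and reduces it to percent time with significant coherence per
#' band. Optionally adds the VAR(1) temporal-variability test.
#'
#' @param study_dir Directory written by [gen_study()] (raw recordings, BOLD
#'   tables and `manifest.json`).
#' @param bands List of [band_spec()] (default [default_bands()]); HBI pairs
#'   are summarised over the HBI bands and RVT pairs over the RVT band(s),
#'   identified by the band name prefix.
#' @param n_boot Bootstrap pairs for the coherence thresholds (default 300).
#' @param alpha Significance level (default 0.05).
#' @param ar_order AR null-model order, 1 (default) or 9.
#' @param dj,s0,max_period Scale-grid parameters (see [build_scale_grid()]);
#'   `NULL` means the grid defaults for the study's length and frame spacing.
#' @param hbi_window HBI sliding-window width in seconds (default 6).
#' @param variability If TRUE also run [variability_test()] per pair with
#'   `var_n_boot` bootstrap pairs.
#' @param var_n_boot Bootstrap pairs for the variability null (default 1000).
#' @param signals Which physiological signals to analyse (default both).
#' @param seed Integer seed for all bootstrap draws.
#' @param verbose Print per-stage progress.
#' @return An object of class `study_result`: `table` (the subject x signal x
#'   network x band data frame of percent time significant), `details` (per
#'   subject/signal/network: coherence fields are not retained, but
#'   per-frequency profiles and variability profiles are), and `config`.
#' @export
run_pipeline <- function(study_dir, bands = default_bands(), n_boot = 300,
                         alpha = 0.05, ar_order = 1L, dj = 1 / 12, s0 = NULL,
                         max_period = NULL, hbi_window = 6,
                         variability = FALSE, var_n_boot = 1000,
                         signals = c("HBI", "RVT"), seed = 1L,
                         verbose = FALSE) {
  signals <- match.arg(signals, several.ok = TRUE)
  manifest_path <- file.path(study_dir, "manifest.json")
  if (!file.exists(manifest_path)) stop("no manifest.json in `study_dir`", call. = FALSE)
  man <- jsonlite::read_json(manifest_path, simplifyVector = TRUE)
  n <- man$n_frames
  dt <- man$dt_frames
  frame_t <- (seq_len(n) - 1) * dt
  if (is.null(s0)) s0 <- 2 * dt
  if (is.null(max_period)) max_period <- n * dt / 2
  grid <- build_scale_grid(dt, n, dj = dj, s0 = s0, max_period = max_period)
  nets <- man$networks
  subj_ids <- names(man$subjects)
  is_hbi_band <- grepl("^HBI", vapply(bands, `[[`, "", "name"))

  rows <- list()
  details <- list()
  for (si in seq_along(subj_ids)) {
    sid <- subj_ids[si]
    if (verbose) message("subject ", sid)
    pulse <- read_physio_recording(file.path(study_dir, paste0(sid, "_pulse.tsv")))
    resp <- read_physio_recording(file.path(study_dir, paste0(sid, "_resp.tsv")))
    bold <- read_bold_table(file.path(study_dir, paste0(sid, "_bold.tsv")), dt = dt)
    peaks <- detect_pulse_peaks(pulse)
    ext <- detect_breath_extrema(resp)
    physio <- list(
      HBI = mean_normalize(compute_hbi(peaks, frame_t, window = hbi_window)),
      RVT = mean_normalize(compute_rvt(ext$maxima, ext$minima, frame_t))
    )[signals]
    details[[sid]] <- list()
    for (sig in names(physio)) {
      sig_bands <- bands[if (sig == "HBI") is_hbi_band else !is_hbi_band]
      ps <- physio[[sig]]
      model_p <- fit_ar(ps, order = ar_order)
      for (netname in nets) {
        bs <- mean_normalize(bold[[netname]])
        model_b <- fit_ar(bs, order = ar_order)
        thr_seed <- as.integer((seed + 7L * si + 13L * match(netname, nets) +
                                  29L * match(sig, names(physio))) %% .Machine$integer.max)
        thr <- bootstrap_thresholds(model_p, model_b, n, dt, grid,
                                    n_boot = n_boot, alpha = alpha,
                                    seed = thr_seed)
        coh <- wtc(ps, bs, grid)
        mask <- significance_mask(coh, thr)
        prof <- percent_time_significant(mask, coh, bands = sig_bands)
        det <- list(profile = prof, phase = categorize_phase(coh, mask))
        if (variability) {
          det$variability <- variability_test(ps, bs, grid,
                                              n_boot = var_n_boot,
                                              alpha = alpha,
                                              seed = thr_seed + 1L)
        }
        details[[sid]][[paste(sig, netname, sep = ".")]] <- det
        for (bi in seq_len(nrow(prof$per_band))) {
          rows[[length(rows) + 1]] <- data.frame(
            subject = sid, signal = sig, network = netname,
            band = prof$per_band$band[bi], pct_sig = prof$per_band$pct_sig[bi]
          )
        }
      }
    }
  }
  structure(
    list(table = do.call(rbind, rows), details = details,
         config = list(bands = bands, n_boot = n_boot, alpha = alpha,
                       ar_order = ar_order, dj = dj, s0 = s0,
                       max_period = max_period, hbi_window = hbi_window,
                       variability = variability, var_n_boot = var_n_boot,
                       seed = seed, grid = grid)),
    class = "study_result"
  )
}

#' @export
print.study_result <- function(x, ...) {
  cat(sprintf("<study_result> %d rows (%d subjects x signals x networks x bands)\n",
              nrow(x$table), length(unique(x$table$subject))))
  invisible(x)
}

# wide subject x network matrix for one (signal, band)
study_wide <- function(tbl, signal, band) {
  sub <- tbl[tbl$signal == signal & tbl$band == band, ]
  if (!nrow(sub)) stop("no rows for that (signal, band)", call. = FALSE)
  w <- stats::reshape(sub[, c("subject", "network", "pct_sig")],
                      idvar = "subject", timevar = "network",
                      direction = "wide")
  m <- as.matrix(w[, -1, drop = FALSE])
  colnames(m) <- sub("^pct_sig\\.", "", colnames(m))
  rownames(m) <- w$subject
  if (anyNA(m)) stop("incomplete subject x network crossing", call. = FALSE)
  m
}

#' One-way repeated-measures ANOVA across networks
#'
#' Compares percent time with significant coherence between the seven
#' networks for one (signal, band), with subject as the repeated factor.
#' Both the uncorrected p-value and the Greenhouse-Geisser sphericity
#' correction are reported (the correction's epsilon is computed from the
#' double-centred covariance of the subject x network matrix).
#'
#' @param tbl The `table` element of a [run_pipeline()] result (or any data
#'   frame with columns subject/signal/network/band/pct_sig).
#' @param signal `"HBI"` or `"RVT"`.
#' @param band Band name as in the table.
#' @return List with `F`, `df1`, `df2`, `p`, `gg_epsilon`, `p_gg`.
#' @export
rm_anova <- function(tbl, signal, band) {
  m <- study_wide(tbl, signal, band)
  ns <- nrow(m)
  k <- ncol(m)
  grand <- mean(m)
  ss_cond <- ns * sum((colMeans(m) - grand)^2)
  ss_subj <- k * sum((rowMeans(m) - grand)^2)
  ss_tot <- sum((m - grand)^2)
  ss_err <- ss_tot - ss_cond - ss_subj
  df1 <- k - 1
  df2 <- (k - 1) * (ns - 1)
  if (ss_cond <= 1e-12 * max(ss_tot, 1)) {
    return(list(F = 0, df1 = df1, df2 = df2, p = 1, gg_epsilon = 1, p_gg = 1))
  }
  FF <- (ss_cond / df1) / (ss_err / df2)
  # Greenhouse-Geisser epsilon from the double-centred covariance
  S <- stats::cov(m)
  C <- S - outer(rowMeans(S), colMeans(S), function(a, b) a + b) + mean(S)
  eps <- sum(diag(C))^2 / (df1 * sum(C^2))
  eps <- min(max(eps, 1 / df1), 1)
  list(
    F = FF, df1 = df1, df2 = df2,
    p = stats::pf(FF, df1, df2, lower.tail = FALSE),
    gg_epsilon = eps,
    p_gg = stats::pf(FF, df1 * eps, df2 * eps, lower.tail = FALSE)
  )
}

bonf_stars <- function(p, family) {
  base <- 0.05 / family
  if (p < base * 1e-3) "****" else if (p < base * 1e-2) "***" else
    if (p < base * 1e-1) "**" else if (p < base) "*" else "ns"
}

#' Post-hoc paired t-tests with Bonferroni correction
#'
#' All pairwise network contrasts (21 pairs, the Bonferroni family size) for
#' one (signal, band). Pairs with zero within-pair variance but a non-zero
#' mean difference are flagged (`infinite_t`) and given the smallest
#' representable p. Significance stars follow the alpha/family convention
#' (`*` p < 0.05/21 = 0.0024, each further star one decade smaller).
#'
#' @inheritParams rm_anova
#' @return Data frame `(network1, network2, t, p, p_bonferroni, significant,
#'   sig_stars, infinite_t)`.
#' @export
paired_tests_bonferroni <- function(tbl, signal, band) {
  m <- study_wide(tbl, signal, band)
  nets <- colnames(m)
  pairs <- utils::combn(nets, 2)
  fam <- ncol(pairs)
  out <- lapply(seq_len(fam), function(i) {
    a <- m[, pairs[1, i]]
    b <- m[, pairs[2, i]]
    d <- a - b
    inf_t <- FALSE
    if (stats::sd(d) < 1e-12) {
      if (abs(mean(d)) < 1e-12) {
        tval <- 0; p <- 1
      } else {
        tval <- sign(mean(d)) * Inf; p <- .Machine$double.xmin; inf_t <- TRUE
      }
    } else {
      tt <- stats::t.test(a, b, paired = TRUE)
      tval <- unname(tt$statistic); p <- tt$p.value
    }
    data.frame(network1 = pairs[1, i], network2 = pairs[2, i], t = tval,
               p = p, p_bonferroni = min(1, p * fam),
               significant = p * fam < 0.05,
               sig_stars = bonf_stars(p, fam), infinite_t = inf_t)
  })
  out <- do.call(rbind, out)
  rownames(out) <- NULL
  out
}

#' Per-network low-vs-high band contrast for HBI
#'
#' Paired t-test per network comparing percent time significant between the
#' low (0.05-0.15 Hz) and high (0.15-0.4 Hz) heartbeat-interval bands,
#' Bonferroni-corrected at family size 7 (one test per network).
#'
#' @param tbl As in [rm_anova()].
#' @param band_low,band_high Band names (defaults match [default_bands()]).
#' @return Data frame `(network, t, p, p_bonferroni, significant, sig_stars)`.
#' @export
band_contrast_tests <- function(tbl, band_low = "HBI-low", band_high = "HBI-high") {
  lo <- study_wide(tbl, "HBI", band_low)
  hi <- study_wide(tbl, "HBI", band_high)
  nets <- colnames(lo)
  fam <- length(nets)
  out <- lapply(nets, function(netname) {
    d <- lo[, netname] - hi[rownames(lo), netname]
    if (stats::sd(d) < 1e-12) {
      tval <- if (abs(mean(d)) < 1e-12) 0 else sign(mean(d)) * Inf
      p <- if (tval == 0) 1 else .Machine$double.xmin
    } else {
      tt <- stats::t.test(lo[, netname], hi[rownames(lo), netname], paired = TRUE)
      tval <- unname(tt$statistic); p <- tt$p.value
    }
    data.frame(network = netname, t = tval, p = p,
               p_bonferroni = min(1, p * fam), significant = p * fam < 0.05,
               sig_stars = bonf_stars(p, fam))
  })
  out <- do.call(rbind, out)
  rownames(out) <- NULL
  out
}

#' Write a study table as text
#'
#' Tab-separated `(subject, signal, network, band, pct_sig)`.
#'
#' @param result A [run_pipeline()] result or its `table`.
#' @param path Output path.
#' @export
write_study_table <- function(result, path) {
  tbl <- if (inherits(result, "study_result")) result$table else result
  utils::write.table(tbl, path, sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(path)
}
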