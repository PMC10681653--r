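---
title: "Time-frequency coherence between brain and body: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Time-frequency coherence between brain and body: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(physiowtc)
```

## The problem

Resting-state fMRI measures blood-oxygen-level-dependent (BOLD) fluctuations
that mix neuronal activity with systemic physiology: beat-to-beat changes in
heart rate and breath-to-breath changes in respiratory depth both modulate
cerebral blood flow and oxygenation in the same low-frequency range as
neurogenic hemodynamics. Whether a network's BOLD signal is *coherent* with
heartbeat-interval (HBI) or respiration-volume-per-time (RVT) dynamics — and
at which frequencies, with which lead/lag relationship, and how stably over
time — therefore carries information about autonomic versus vascular drivers
of apparent "connectivity".

`physiowtc` implements that analysis as a reusable pipeline: wavelet
transform coherence (WTC) between network-averaged BOLD series and
frame-aligned HBI/RVT series, Monte-Carlo significance of coherence
magnitude, phase-offset categorisation, a bootstrap test of temporal
variability of coherence, and group-level summaries. Because the motivating
recordings (fast-TR human rsfMRI with simultaneous pulse oximetry and
respiratory bellows) cannot ship with a package, a synthetic-data generator
with known ground-truth coupling stands in for them everywhere, and is
itself first-class, tested code.

## From raw sensors to frame-aligned series

Pulse-oximeter and bellows traces arrive as two-column (time, value) text at
the peripheral sampling rate (400 Hz by default). Processing follows the
conventional event-based route:

* **HBI** — systolic peaks are detected as local maxima over an adaptive
  amplitude threshold with a refractory spacing, after a zero-phase 10 Hz
  low-pass. For each imaging frame, the beat-to-beat durations whose
  *midpoints* fall in a 6 s window centred on the frame are averaged, and
  the inverse of that average is returned. Midpoint membership is a design
  choice: it is symmetric and unambiguous where a duration straddles the
  window edge. Frames whose window holds no duration are filled with the
  nearest valid value and flagged rather than interpolated, so no structure
  is invented. The name "heartbeat interval" and the inverse (rate-like)
  definition coexist in the field; both forms are exposed
  (`compute_hbi(form =)`) and the inverse form is the default. At
  physiological modulation depths the two are monotone transforms of one
  another and give the same coherence band structure.
* **RVT** — the bellows trace is zero-phase low-pass filtered at 1 Hz,
  alternating maxima/minima are extracted (the lesser of two same-kind
  neighbours is dropped to enforce alternation), each maximum is paired with
  the following minimum, and the per-breath value
  (max − min) / (spacing between consecutive maxima) is linearly
  interpolated to the frame centres, holding boundary values outside the
  first/last breath.
* All series (HBI, RVT, per-network BOLD) are mean-normalized. Subtracting
  the mean is the default; a divide-by-mean (percent-change) form is also
  provided. The coherence estimator is affine-invariant, so the choice
  affects units only — a property the test suite asserts exactly.

## The estimator

The continuous wavelet transform of a series $x_n$ with step $\Delta t$ is

$$W_X(n, s) = \sqrt{\tfrac{\Delta t}{s}} \sum_{n'} x_{n'}\,
  \psi_0^*\!\big((n'-n)\tfrac{\Delta t}{s}\big), \qquad
  \psi_0(\eta) = \pi^{-1/4} e^{i\omega_0 \eta} e^{-\eta^2/2},$$

with the Morlet centre frequency $\omega_0 = 6$, for which the Fourier
period is $T = \frac{4\pi}{\omega_0 + \sqrt{2+\omega_0^2}} s \approx 1.033\,s$
— scale and period axes are essentially interchangeable (the package uses
the exact factor throughout). The transform is evaluated by FFT convolution
with zero-padding to the next power of two of at least twice the record
length; at that padding the circular product reproduces the direct
convolution sum to machine precision, which the tests verify against a
brute-force double-sum oracle. The series mean is removed first, making the
estimator exactly invariant to affine rescaling of its inputs.

The cross-wavelet transform is $W_{XY} = W_X W_Y^*$, and coherence is

$$R^2(n,s) = \frac{\big|S\big(s^{-1} W_{XY}\big)\big|^2}
 {S\big(s^{-1}|W_X|^2\big)\; S\big(s^{-1}|W_Y|^2\big)},$$

where $S$ smooths in time with a unit-mass Gaussian of standard deviation
$s/\sqrt{2}$ and across scales with a unit-mass boxcar spanning 0.6
decorrelation widths ($0.6/dj$ voices). Without $S$ the ratio is identically
1 by Cauchy–Schwarz — a regression test guards that the smoothing is
actually applied. Both kernel constants are exposed (`smooth_dj0`,
and the time kernel scales with the wavelet itself). Kernels are
renormalized at the record edges so a constant field passes through
unchanged and $R^2$ stays in $[0, 1]$ up to $10^{-9}$, after which it is
clipped. Phase is taken from the smoothed cross spectrum so that phase and
magnitude describe the same estimator.

**Scale grid.** $s_j = s_0 2^{j\,dj}$ with $dj = 1/12$ (12 voices per
octave), $s_0 = 2\Delta t$, up to a Fourier period of half the record. For
1200 frames at 0.72 s this spans ~0.67 Hz down to ~0.0023 Hz, covering the
HBI (0.05–0.15, 0.15–0.4 Hz) and RVT (0.02–0.04 Hz) bands with margin.

**Cone of influence.** Estimates within one wavelet e-folding time
($\sqrt{2}s$) of either record edge are unreliable; the trustworthy region
at time $t$ is limited to periods below
$1.033 \cdot \min(t - t_1, t_N - t)/\sqrt{2}$. Every aggregate metric in the
package excludes in-cone points, and tests assert that arbitrary junk placed
inside the cone cannot change any metric.

**Degenerate inputs.** Constant series are rejected with an error rather
than returning 0/0 fields.

## Significance of coherence magnitude

Each input series is modelled as an autoregressive process (order 1 by
default, order 9 available for cardiorespiratory series), fitted by
Yule–Walker. Three hundred independent pairs are simulated from the two
marginal models, coherence is computed for each, and the per-scale 95th
percentile of the pooled out-of-cone $R^2$ values is the significance
threshold. Pooling across time points and bootstrap pairs is a design
choice — the alternative (a per-(scale, time) distribution) discards most of
the sample for no benefit, since the null is time-stationary by
construction. Scales with no out-of-cone points (periods longer than the
cone allows anywhere) carry `NA` thresholds and are excluded downstream.

Calibration is verified empirically: with thresholds built from 300
bootstrap pairs and validated on 200 fresh independent AR(1) pairs
(φ = 0.5, 1200 frames), per-scale coverage sits at 95 ± 1% wherever the
validation sample carries enough information. The per-scale check is
restricted to scales whose *effective* number of independent validation
points — pooled points divided by the time-smoothing span of about
$2.8\,s/\Delta t$ samples — is at least 2000; at the largest scales a
handful of effectively independent points per record makes a ±1-point
comparison statistically meaningless, though the all-scale mean still sits
within a fraction of a point of the nominal level. `scripts/acceptance.R`
recomputes exactly this quantity.

Spectrum-preserving surrogates (`make_phase_shuffled_null`) complement the
AR null: the Fourier phases of the positive-frequency bins are replaced by
i.i.d. uniform draws under Hermitian symmetry, preserving the amplitude
spectrum bin-for-bin (to $10^{-10}$) while destroying any phase alignment
with a partner signal — the control for "is this coherence just a power
profile?".

## Phase categories and lags

Significant out-of-cone points are assigned to four half-open quarter-circle
arcs centred at 0, $\pi/2$, $\pi$ and $-\pi/2$ (half-width $\pi/4$). The
half-open convention `[centre − π/4, centre + π/4)` makes the partition
exact: the per-bin profiles sum to the unsplit profile to $10^{-9}$, which
is asserted, not assumed. The sign convention is likewise *asserted* by a
constructed-lag test rather than inherited from any toolbox: with the
physiological series as signal of interest and BOLD as reference (phase
$= \arg S(s^{-1} W_{\mathrm{physio}} W_{\mathrm{BOLD}}^*)$), a physiological
copy delayed by a quarter period produces phase $-\pi/2$, labelled "BOLD
leading"; $+\pi/2$ is "physio leading". Because phase is circular,
"lagging by three quarters" and "leading by one quarter" are the same
number; the labels follow the usage in which $\pm\pi/2$ are read as the
nearest-lag interpretation.

As a non-circular cross-check, `xcorr_peak_lag` band-passes both series
(zero-phase, 4th-order Butterworth applied forward–backward) and returns
the lag of the normalized cross-correlation maximum, with positive lag
meaning the physiological series trails BOLD. For narrowband signals the
correlation function is near-periodic, so `max_lag` should stay below half
the band's central period; the function itself reports the global argmax in
the window it is given.

## Temporal variability of coherence

To ask whether coherence *varies in time* more than a stationary linear
relationship would produce, the complex coherence
$z(t) = R^2(t)e^{i\phi(t)}$ is formed per scale over out-of-cone times and
its complex variance $\sigma^2 = \langle (z-\mu_z)(z-\mu_z)^* \rangle$
(sample mean, divisor $n$) is compared against a null built by fitting a
VAR(1) to the pair (ordinary least squares per equation, Gaussian
innovations from the fitted covariance — the model class is standard, the
estimator and innovation law are design choices) and simulating 1000
bootstrap pairs. Unlike the independent-AR null above, the VAR null
*preserves* the pair's stationary cross-dependence, so it isolates
time-variation specifically; a test verifies that bootstrap pairs reproduce
the fitted pair's mean coherence level. Scales with fewer than 8 out-of-cone
points are reported missing rather than extrapolated. Cohorts are
summarised as the percentage of participants whose variability flag is set
at each frequency.

## The synthetic study

The generator emulates the acquisition geometry of a 15-minute fast-TR
resting-state session: 1200 frames at 0.72 s, peripheral recordings at
400 Hz, seven network-averaged BOLD series (DAN, DMN, FPN, LN, SMN, VAN,
VN). Its components:

* AR(1) backgrounds for BOLD and physiology (default φ = 0.5, unit
  innovation sd) — the same model family the significance machinery
  assumes, so calibration experiments are exact.
* A pulse waveform built as a raised-cosine train: pulse morphology carries
  no information in this analysis, only peak times do, so the simplest
  recoverable shape is used. Beat intervals follow a slowly varying profile;
  heart-rate modulation at the coupling frequency (default depth 5%, a
  realistic resting heart-rate-variability magnitude) encodes the
  physiological side of the coupling.
* A bellows waveform oscillating at 0.25 Hz whose per-breath
  (peak − trough)/period tracks a respiratory-depth profile, modulated by
  default at 0.03 Hz — inside the 0.02–0.04 Hz band where RVT
  predominantly fluctuates at rest.
* Coupling injected *additively* at the frame rate: a shared sinusoid at the
  coupling frequency (amplitude expressed as a multiple of the background's
  stationary sd) added to both sides, the physiological copy delayed by
  `phase_lag/(2π f)` seconds, gated by on/off epochs. An additive injection,
  rather than a hemodynamic forward model, keeps the ground truth exact: the
  estimator under test is agnostic to the generative physiology, and
  recovery of frequency, phase and epochs can be asserted against known
  numbers.
* Per-subject parameters jittered around a template; per-subject seeds are
  the master seed plus a fixed offset of 1000 per subject, so studies are
  reproducible byte-for-byte.

What the generator does *not* emulate — hemodynamic response convolution,
1/f BOLD spectra beyond AR(1), waveform pathology, motion, scanner drift —
bounds what passing tests show: they validate the estimator and its
calibration, not robustness to every artifact of real recordings.

## Problem sizes used by the test suite

Monte-Carlo experiments in the tests run at sizes chosen to make their
sampling error small relative to the asserted tolerances while keeping the
default suite comfortably runnable on a laptop: threshold calibration at the
full study geometry (1200 frames, 300 bootstrap + 200 validation pairs);
variability-test calibration on 100 replicate datasets of 256 frames with
200 bootstrap pairs each, and its power check on 50 seeds of 400 frames with
mid-record-only coupling at four background standard deviations; cohort
recovery on three replicate ten-subject studies of 480 frames with
bootstrap size 64 and an eight-voice grid. Parameter-recovery checks use
n = 5000 averaged over 100 seeds. The full-size defaults (300/1000
bootstrap pairs, 12 voices per octave) remain the package defaults
throughout.

## Known limitations

* Thresholds are fitted per signal pair (as the per-input-signal modelling
  implies); with 2 signals × 7 networks × hundreds of bootstrap pairs the
  pipeline is Monte-Carlo-bound, and `n_boot` is the knob to trade accuracy
  for time.
* The AR/VAR nulls are Gaussian and linear; heavy-tailed or nonlinear
  couplings are outside their model class.
* Phase lead/lag labels are quarter-cycle interpretations of circular
  quantities; the cross-correlation lag check is the recommended
  disambiguation.
* The repeated-measures ANOVA reports both uncorrected and
  Greenhouse–Geisser p-values; neither is privileged, because sphericity
  behaviour depends on the cohort at hand.
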