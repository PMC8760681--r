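---
title: "Quantifying optogenetic silencing in long-term LFP recordings"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying optogenetic silencing in long-term LFP recordings}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(optolfp)
```

## The experimental setting

optolfp quantifies multi-hour local field potential (LFP) recordings from
freely moving mice carrying an optogenetic construct in hippocampal CA1.
A session lasts three hours: a pre-recording hour, a "light ON" hour in
which brief (10-ms) blue-light pulses are delivered every 10 or 20 s
(0.1 or 0.05 Hz), and a post-recording hour. The last 10 minutes of the
light hour use fading light intensity and are excluded, so the analysis
window of the light hour is its first 50 minutes. Potassium-channel-based
silencers (bPAC + SthK, driven as a pulsed suppressor) reduce the LFP
magnitude after each pulse with slow exponential recovery; bPAC alone acts
as an enhancer. In the intrahippocampal kainate model of mesial temporal
lobe epilepsy, the ipsilateral hippocampus (`HCi`) additionally produces
interictal sharp-wave spikes clustered into bursts, which may or may not
propagate to the contralateral channel (`HCc`).

## The magnitude statistic: line length

The primary magnitude measure is the line length of the 500-Hz
downsampled trace,

$$ L = \frac{\sum_{k} \left| x(k-1) - x(k) \right|}{t} \quad [\mathrm{mV/s}], $$

the total variation per unit time. It grows with both amplitude and
frequency, which makes it a robust single-number summary of "how much
signal" a window contains. Three analyses build on it:

* **Hour-wise**: \(L\) per session hour, reported as differences from the
  first (baseline) hour. Healthy animals show a spontaneous decline over
  the session (habituation: falling arousal and exploration), so
  stimulated sessions are always read against reference sessions.
* **Pulse-triggered**: for every pulse \(p\), \(L\) over the 2-s window
  before the onset (`before`) and the 2-s window starting at the pulse
  offset (`after`), plus a baseline window at the same clock offset in the
  pre-recording hour (`pre`). At 0.05 Hz with fast recovery the signal
  returns to baseline before the next pulse (`before` \(\approx\) `pre`);
  at 0.1 Hz suppression accumulates (`pre` > `before` > `after`).
* **Masking**: annotated generalized-seizure (GS) intervals are excluded,
  not zero-filled — excluded samples contribute neither differences nor
  duration, and differences across the gap are never counted. Zero-filling
  would deflate \(L\) at the mask edges; shrinking the effective duration
  keeps the statistic unbiased on the retained data.

Windows are half-open `[a, b)` throughout: sample `i` covers
`[i/fs, (i+1)/fs)`, and a sample on a boundary belongs to the following
window. The after-window starts at the pulse *offset* (onset + 10 ms): the
illumination artifact itself is negligible at 500 Hz but is excluded for
cleanliness. The 2-s before-window abuts the pulse onset with no guard gap.
Pulses whose three windows touch a masked sample are dropped from all
three series, keeping the triplets aligned.

## Spectral analysis

Power spectral densities use Welch's method on raw-rate data with a
periodogram length of ten times the sampling rate (0.1-Hz resolution),
Hanning window, and per-segment mean removal (the acquisition chain is
AC-coupled at 1 Hz, so no information lives at DC). The periodogram
overlap is 50% — a conventional choice documented here because only the
periodogram length is dictated by the method being mirrored. The density
is one-sided and normalized so its integral equals the signal variance
(Parseval, verified to 2% in the tests). Band power is the area under the
density between exact band edges — delta 1–4, theta 4–12, beta 12–30,
gamma 30–120 Hz — by trapezoidal integration with interpolated endpoints,
which makes power exactly additive over adjacent bands.

Spectrograms use 0.5-s Hanning segments, 0.25-s hops, zero-padded to an
FFT length of ten times the sampling rate.

For masked data the hourly PSD is the duration-weighted average of Welch
spectra over the maximal contiguous unmasked runs of at least one
periodogram length; an hour with no such run is an error rather than a
silently degraded estimate.

## Epileptiform activity

Published burst classifiers for this model are semi-automated and
ML-based; optolfp instead ships a transparent, fully deterministic
threshold pipeline whose parameters are all exposed (the defaults are
package choices, not values from any published classifier):

1. **Spikes**: local extrema of the 5–80 Hz band-passed 500-Hz trace
   exceeding 5 robust SDs (MAD × 1.4826 — plain SD would be inflated by
   the spikes themselves), thinned to one event per 80-ms refractory
   window.
2. **Bursts**: maximal spike runs with inter-spike gaps ≤ 2 s and ≥ 5
   members, padded by half a kernel width.
3. **Load classes**: intra-burst rate `r = members / duration`; `high`
   when `r ≥ 1` Hz and duration ≥ 10 s, `medium` when `r ≥ 0.5` Hz, else
   `low`.
4. **Burst ratio**: total high-load burst time divided by session time.
   Sessions containing a GS are dropped (reported missing), since the
   long postictal suppression distorts every downstream number.

On synthetic ground truth with 8-SD spikes, detection recovers ≥ 95% of
spikes within ±10 ms, burst intervals overlap truth with Jaccard ≥ 0.8,
and the estimated burst ratio lands within ±0.03 of the injected
fraction (see `tests/testthat/test-acceptance.R`).

A cross-channel GS screener (`detect_gs()`: both channels rhythmic at
3–8 Hz above 4 robust SDs for ≥ 10 s, followed by ≥ 30 s of RMS below half
baseline) is provided for triage, but annotation-driven masking remains
authoritative — GS identification in the modelled experiments was visual.

## The synthetic session generator

Every stage is validated against `simulate_experiment()`, which composes,
per channel:

```
background(t) * habituation(hour) * pulse_gain(t)  +  bursts  +  seizures
```

* **Background**: 1/f\(^\beta\) noise (β = 1, RMS 0.10 mV, flattened below
  1 Hz and band-limited to 200 Hz so the configured RMS lands in the
  analysis band at any raw rate) plus band-pass-filtered white-noise
  oscillators — theta (7 ± 1.5 Hz, 0.15 mV RMS), beta (20 ± 4 Hz,
  0.05 mV), gamma (40 ± 15 Hz, 0.04 mV). Each component is scaled to its
  RMS empirically, so band powers are exact by construction. A single
  global `amplitude_scale = 1.92` calibrates the composite so the hour-1
  line length at 500 Hz is ≈ 50 mV/s, the baseline magnitude the analyses
  are read against; it was fixed once by closed measurement of the default
  composite and is not a tuning knob.
* **Habituation** is a stepwise per-hour gain, default
  `[1.00, 0.84, 0.79]`: only per-hour magnitudes are meaningful for the
  hour-wise statistic, so a continuous decay would add a free parameter
  without adding testability. With an hour-1 line length of 50 mV/s these
  gains give hour-wise deltas of ≈ −8 and ≈ −10.5 mV/s.
* **Pulse gain**: \(g(t) = 1 \mp s \sum_k e^{-(t-p_k)/\tau}\,[t \ge p_k]\)
  (suppression/enhancement), clipped at 0.05, identity outside the light
  hour. The default \((s, \tau) = (0.25, 12\,\mathrm{s})\) gives a
  steady-state after/pre ratio of
  \(1 - s\,\frac{\tau}{2}\big(e^{-w/\tau} - e^{-(w+2)/\tau}\big)/\big(1-e^{-T/\tau}\big) \approx 0.59\)
  at 0.1 Hz — matched to the observed after-pulse suppression — and full
  recovery at 0.05 Hz only for shorter \(\tau\). A model property worth
  knowing: with these defaults the steady-state *before*/pre ratio at
  0.1 Hz is ≈ 0.79, somewhat shallower than the ≈ 0.74 observed in vivo;
  matching both ratios simultaneously would need \((s,\tau) \approx
  (0.19, 17\,\mathrm{s})\). The kinetics of the silencer's photocurrent in
  vivo are unknown, so \(\tau\) is deliberately a free parameter.
* **Bursts**: biphasic sharp-wave kernels (40-ms width, 8 × background
  SD) at jittered-regular spike times (2 Hz) inside non-overlapping burst
  windows; ground truth records spike times, burst intervals and intended
  load class. Multiplicativity of the gain means line length scales with
  mean gain on stationary traces (verified to 3%), which is what makes
  parameter recovery meaningful.
* **Seizures**: a sharpened 3–8 Hz spike-and-wave discharge added to both
  channels, followed by multiplicative postictal depression, plus a `GS`
  annotation.

Everything is deterministic given the master seed (per-channel and
per-stage sub-seeds are derived arithmetically, all below 2^31), down to
byte-identical EDF exports.

What the generator does *not* emulate: movement and chewing artifacts,
electrode drift, state transitions (sleep/wake), true seizure morphology
beyond a stylized spike-and-wave, and any biophysics of the silencer
(no cAMP kinetics, no conductances). Passing tests therefore demonstrate
the *analysis* is correct and recoverable under the assumed signal model,
not that the model captures every property of in vivo data.

## Statistics

The battery mirrors the analysis conventions of the modelled experiments:
technical replicates (two sessions per type) are averaged per animal
before testing, so `n` is the number of animals; p-values are two-tailed;
every result records the significance level alongside the p-value, with
Bonferroni scaling where a family of planned comparisons shares it
(`alpha = 0.025` for the two hour-wise baseline contrasts). One-sample and
paired t, one-way/RM ANOVA with Tukey, two-way RM ANOVA (band × hour)
with Dunnett, Friedman/Kruskal–Wallis with Dunn, and Pearson correlation
are provided; RM ANOVA applies no sphericity correction (a documented
limitation switch, matching the mirrored convention), Dunn uses Bonferroni
scaling over tested pairs (the original software's scaling is not
documented), and parametric vs rank-based dispatch is config-driven, not
decided by a normality test. Identities used as oracles: RM-ANOVA F equals
the squared paired-t statistic on two conditions (to 1e-9), and the
one-/two-way RM decompositions agree with `aov()` error strata.

Degenerate-input conventions: zero-variance t tests and correlations are
errors, not p = 1; a zero effect sum of squares yields F = 0, p = 1; rank
tests on all-equal data return statistic 0 (the tie correction is
degenerate there).

## Numerical choices

* **Decimation** (10 kHz → 500 Hz for line length): symmetric FIR low-pass
  with cutoff `0.4 * fs_out`, applied with exact group-delay compensation —
  zero phase, so the line length is not biased by phase distortion.
  Passband flat to 1%, stopband below −20 dB at the output Nyquist.
  Non-integer decimation factors are refused rather than resampled.
* **EDF I/O**: 16-bit EDF with one data record per second and a symmetric
  physical range per channel with 0.01% headroom; worst-case quantization
  error is `range/65535` (≈ 3 × 10⁻⁴ mV at ±10 mV). Session metadata
  round-trips through the recording-identification header field. Events
  travel in a `label,onset_s,duration_s` CSV; pulse onsets use the label
  `pulse`, seizures `GS`.
* **Problem sizes**: tests and the acceptance script simulate sessions at
  a 1 kHz (or 500 Hz) raw rate with full-length 3600-s hours where the
  pulse schedule matters and 600-s hours elsewhere; the generator's
  spectral content is identical below 200 Hz regardless of raw rate, so
  these runs exercise exactly the code paths used at 10 kHz.

## Worked example

```{r example, eval = FALSE}
lay <- session_layout(3600, 600)
cfg <- sim_config(fs_raw = 1000, layout = lay, channels = "right",
                  session = "stim_0.1", habituation = c(1, 1, 1),
                  pulse = list(mode = "suppress", depth = 0.25, tau = 12,
                               frequency = 0.1, pulse_width = 0.01,
                               channels = NULL),
                  seed = 1)
sim <- simulate_experiment(cfg)
ms <- downsample(masked_signal(sim$recording$channels$right, 1000), fs_out = 500)
pr <- pulse_triggered(ms, sim$recording$pulses, lay)
glance(pr)
autoplot(pr)
```

## Known limitations

* The burst classifier is a deterministic stand-in with package-default
  thresholds; burst ratios from real recordings are comparable across
  sessions analyzed with the same thresholds but not directly with
  numbers produced by other classifiers.
* Whether pulse trains start exactly on the light-ON boundary in real
  recordings is unknown; the simulator assumes they do, and the analysis
  drops the first pulse (its before-window has no matched-pre offset).
* The PSD treatment of GS periods in healthy animals (run-wise masking
  here) and the Welch overlap are package conventions where the mirrored
  method is silent.
* No artifact rejection beyond annotated GS intervals, no notch filter,
  no multitaper or wavelet spectra, no 1/f parametric fits.
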