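---
title: "Detecting transient beta bursts and their BOLD correlates"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Detecting transient beta bursts and their BOLD correlates}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(betaburst)
```

## The model

Beta-band (13–30 Hz) activity in sensorimotor cortex is not a sustained
oscillation but a sequence of brief, stereotyped *bursts*, typically shorter
than 150 ms. Smooth beta-power changes seen in trial-averaged data — most
prominently the post-movement beta rebound (PMBR), the elevation of beta
power roughly 0.5–1 s after a motor response — reflect modulation of the
*probability* of these bursts. betaburst treats bursts as point events:
it detects them one at a time in a continuous single-channel time course,
converts the event times into rate statistics around a working-memory task,
and regresses a concurrently acquired BOLD series on the burst times.

### Burst detection

The detector is a fixed, deterministic chain:

1. **Time–frequency decomposition.** Complex Morlet wavelets, 5 cycles,
   frequencies 1–40 Hz at 1-Hz steps. Power is the squared magnitude of the
   wavelet coefficient at every sample; the time axis stays at the signal
   sampling rate.
2. **Smoothing.** A separable 2-D Gaussian filter with standard deviations
   1 Hz (frequency) and 6 ms (time), truncated at ±4 SD, renormalised to
   unit sum, applied with mirror-reflected boundaries.
3. **Peak picking.** A spectrogram cell is a candidate burst iff its power
   strictly exceeds the morphological dilation of the image with a 5×5
   structuring element of ones with a zero centre — i.e. iff it is strictly
   greater than all of its (up to 24) in-bounds neighbours. Ties (plateaus)
   are never peaks.
4. **Thresholding.** A candidate is kept iff its power is at least 6 times
   the median power across all time points at the peak frequency. The
   median is taken on the smoothed spectrogram (a flag switches to raw).
5. **Band restriction and edge handling.** Events are restricted to peak
   frequencies in the configured beta band (default 13–30 Hz, the
   conventional definition), and events within half a wavelet support of
   either recording edge are dropped, because the transform is unreliable
   there.

Because the threshold is a *ratio* to the per-frequency median, detection is
invariant to rescaling the signal by any positive constant — the detector
needs no amplitude calibration.

### Wavelet normalisation

The per-frequency wavelet scaling deserves a note, because one common claim
about it is only half true. The median-*ratio* threshold is indeed
invariant to normalisation: rescaling a whole frequency row rescales its
median equally. But the *location* of a peak across frequency rows is not
invariant. A 5-cycle wavelet has bandwidth proportional to its frequency
(σ_f = f/5), so per-frequency scalings tilt the spectrogram along the
frequency axis:

* **energy** (unit L2 norm, the default): sustained tones localise exactly
  at their own frequency, but the peak frequency of a brief transient is
  biased upward by roughly 1–2 Hz in the beta band;
* **peak** (unit time-domain peak): near-unbiased for broadband transients,
  but tones localise about 1 Hz low;
* **amplitude** (unit peak frequency response): equal tone magnitude at all
  frequencies, with the largest upward transient bias (about +3 Hz).

No choice is bias-free for both tones and transients; this is the
time–frequency trade-off of constant-Q analysis, not an implementation
artifact. The default follows the conventional unit-energy choice; all
three are available via the `norm` argument of `morlet_tfr()` and
`detection_config()`.

### What the detector can and cannot resolve

Two hard limits are worth knowing before interpreting per-event
benchmarks, both visible in this package's own simulations
(`scripts/acceptance.R` reports the measured numbers):

* **Frequency assignment of very short bursts.** A 50–100-ms burst at
  20 Hz contains one to two cycles. Its spectral profile is nearly flat
  over several Hz, and it is shorter than the 5-cycle analysis wavelet, so
  background-noise ripples decide where within the broad blob the argmax
  lands. At any realistic amplitude, a substantial fraction of sub-100-ms
  bursts is assigned a peak frequency more than 2 Hz from the injected
  carrier. Matching detected events to ground truth at ±2 Hz therefore
  caps recall well below 1 even when essentially every burst produces a
  detected event at the right *time* (±25 ms matching alone succeeds for
  ~90% of bursts).
* **The noise floor of the 6×-median rule.** On stationary Gaussian 1/f
  background alone, smoothed-spectrogram local maxima exceed 6× the row
  median at a rate of roughly 0.5–0.8 events/s summed over the beta band
  (an exponential-tail calculation gives the same order). Real burst-rate
  estimates therefore ride on a positive offset. Statistics built on
  *differences* of rates — PMBR, condition contrasts, event-locked
  modulation — cancel this offset, which is why they are recovered
  accurately in simulation while raw detected rates overestimate injected
  tonic rates.

These limits motivate the package's emphasis: event *times* feed the rate
and BOLD analyses; per-event frequency labels are reported but should not
be over-interpreted for the shortest bursts.

## Rate statistics

* `condition_rates()` — bursts per second within the union of each
  condition's intervals (rest, 0-back, 1-back, 2-back), half-open
  `[onset, onset + duration)`.
* `event_locked_rate()` — mean bursts/s in 500-ms sliding windows (50-ms
  step by default; the window length matches the display convention for
  burst-rate time courses) relative to locking events.
* `pmbr()` — mean burst rate in windows 0.5–1 s *after* button presses
  minus the rate in baseline windows 3–1.5 s *before* button presses.
  Rates are pooled across responses (total count ÷ total window time);
  per-response averaging is available and identical when no windows are
  dropped. Windows are half-open so no burst is double-counted, and
  windows extending past the recording edge are dropped from numerator and
  denominator alike.
* `group_compare()` — Mann–Whitney U (exact p for pooled n ≤ 20 without
  ties, tie-corrected normal approximation otherwise; effect size
  r = |Z|/√N) or Welch's t with pooled-SD Cohen's d.
* `rm_anova_gg()` — one-way repeated-measures ANOVA with the
  Greenhouse–Geisser ε computed from the sample covariance of the
  conditions. The adjustment is applied unconditionally (no sphericity
  pretest; a flag disables it), a deliberate simplification: ε = 1 exactly
  when sphericity holds trivially (two conditions), and the unadjusted p is
  always reported alongside.
* `associate()` — Spearman ρ with midrank ties; with covariates, both
  variables are residualised by linear regression before rank correlation
  (a rank partial-correlation convention, stated explicitly because
  several inequivalent conventions exist).

## The BOLD model

`build_design_matrix()` reproduces the standard EEG-informed first-level
design: 0-back/1-back/2-back sub-blocks as boxcars, motor responses and
beta bursts as unit impulses, all convolved with the canonical double-gamma
haemodynamic response function (peak delay 6 s, undershoot delay 16 s,
unit dispersions, peak:undershoot 6:1, 32-s support, unit peak).
Regressors are built on a microtime grid of TR/16 so impulses between scan
times are not lost, then sampled at scan acquisition times; boxcar
convolutions are scaled by the grid step so their scale approximates the
convolution integral, while an impulse regressor equals the shifted HRF
exactly. Overlapping epochs of the same condition accumulate, making the
design linear in its events.

`fit_glm()` is plain voxelwise OLS with a t test on a contrast (default:
the burst column). No temporal-derivative columns and no autocorrelation
model are included — a documented simplification relative to full fMRI
pipelines, appropriate here because validation is by recovery on synthetic
data with white noise; a cosine high-pass drift basis is available but off
by default. Voxelwise significance is controlled by Benjamini–Hochberg FDR
(`fdr_bh()`), clusters below 20 voxels are discarded
(`cluster_filter()`, 26-connectivity by default, 6/18 available), and
spherical ROIs of 1-cm radius summarise coefficient maps by voxel-centre
membership in millimetre space (`roi_extract()`, NIfTI affine convention,
0-based voxel indices).

## The synthetic-data generator

Because no real recordings ship with the package, every stage is validated
against a generator that emulates the statistical structure the analysis
assumes.

**Task schedule** (`make_nback_schedule()`): per run, seven task blocks
interspersed with 30-s rests; each block is a random permutation of
0-back/1-back/2-back sub-blocks separated by 10-s rests; each sub-block
shows 15 letters at 2-s intervals with exactly 4 targets. Ten letter ids
are used, id 0 standing for 'X' (the 0-back target); 1-back/2-back letter
sequences are constructed so the match rule holds at exactly the designated
target positions. One run lasts 950 s and contains 315 stimuli (84
targets).

**Behaviour** (`simulate_behavior()`): one response per detected target,
none to non-targets. Hit rates default to 1.00/0.99/0.96 across loads and
reaction times are shifted-lognormal with per-load medians 0.45/0.50/0.58 s
(shift 0.2 s, log-SD 0.25) — near-ceiling accuracy declining with load and
RTs lengthening with load, the qualitative profile of healthy performance
on this task.

**Bursts** (`simulate_burst_times()`, `synthesize_eeg()`): burst times are
a thinned inhomogeneous Poisson process — the minimal point-process model
for events with modulated probability — with rate

> tonic(condition) × poststim(t) + boost × attenuation × rebound(t),

where `poststim` halves the rate for 0.5 s after every stimulus,
`rebound` adds `pmbr_boost` (default 0.6 bursts/s) during 0.5–1 s after
every response, and `group_attenuation` ∈ [0, 1] scales the rebound
(0.5 emulates the attenuated rebound reported in psychosis). Tonic rates
default to 0.50/0.42/0.34/0.26 bursts/s for rest/0-back/1-back/2-back: a
monotone load-dependent decrease of roughly 15% per level, at overall rates
in the range reported for single-trial beta events. The step size was fixed
by a design-time power analysis: with rate-estimate standard errors of
about `sqrt(r/600)` ≈ 0.022 bursts/s at 600 s per condition, and
post-stimulus suppression multiplying task-condition rates by ≈ 0.875,
adjacent effective-rate gaps of at least ~0.07 bursts/s are required for
the monotone ordering to reproduce in ≥95% of replicate recordings —
smaller steps would make the load effect undetectable at single-recording
scale, which is not the regime this phenomenon is reported in.

Each burst is a Hann-enveloped sinusoid with carrier frequency uniform on
15–28 Hz, duration uniform on 0.05–0.145 s (under the 150-ms ceiling
characteristic of beta events), and amplitude 6 background-noise SDs
(yielding peak/median power ratios far above the detection threshold).
Background noise is 1/f^α Gaussian (α = 1, a typical EEG spectrum),
synthesised by spectral shaping. The EEG sampling rate defaults to 250 Hz,
comfortably above four times the highest burst frequency. Ground truth
(times, frequencies, durations, amplitudes) is returned with every
synthesised signal.

**BOLD** (`synthesize_bold()`): each voxel is the analysis design matrix —
built by the same code the fit uses — times true coefficients plus white
Gaussian noise, so recovery tests are exact identities at zero noise.

What the generator does *not* emulate: MR gradient/cardioballistic
artifacts, multi-channel volume conduction, non-Gaussian or non-stationary
background, burst waveform variability, autocorrelated BOLD noise, and
head motion. Passing the package's simulations therefore demonstrates the
correctness of the algorithms under the stated model, not robustness to
everything real concurrent EEG/fMRI contains.

## Numerical choices and degenerate inputs

* Gaussian smoothing kernels are truncated at ±4 SD and renormalised;
  boundaries are mirror-reflected (no edge dimming).
* Peak ties: strict inequality against the centre-excluded dilation, so
  flat plateaus yield no events. Border cells may be peaks (out-of-bounds
  neighbours are ignored), but edge-margin events are dropped afterwards.
* Nearby peaks are *not* merged by default (`min_separation = 0`); an
  optional greedy power-ranked separation filter is provided.
* All event windows are half-open `[lo, hi)`.
* Empty inputs: an empty burst list gives zero rates and an all-zero burst
  regressor; an empty beta band gives an empty event table; degenerate
  groups (zero pooled variance) and constant correlation inputs raise
  typed errors rather than returning NaN.
* Rank-deficient GLM designs fall back to the Moore–Penrose pseudo-inverse
  with a warning and a flag in the fit object.
* All generators accept an integer seed and restore the caller's RNG
  state; identical seeds give bit-identical outputs.

## Simulation scale

The shipped tests and the `scripts/acceptance.R` study use problem sizes
chosen to make Monte-Carlo error small relative to the effects under test
while remaining desk-scale: 600 s of synthetic EEG at 250 Hz for detector
benchmarks; 5,000 responses for PMBR recovery (standard error ≈ 0.02
bursts/s); 200 replicate case-control studies of 30 + 48 participants for
group power; 840 s per condition for load-ordering replication; and
1,000 voxels for GLM calibration and coverage.

## Known limitations

* Burst *durations* and waveforms are not estimated — events are points,
  matching the downstream use of peak times as regressor onsets.
* The per-event frequency label is unreliable for sub-100-ms bursts (see
  the resolution discussion above).
* Detected absolute rates include the threshold's noise floor; prefer
  difference statistics, which this package's own estimators are built
  around.
* The GLM is OLS without prewhitening; its p values are calibrated under
  white noise only.
* Mauchly's sphericity test is not implemented; the Greenhouse–Geisser
  correction is applied unconditionally instead.
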