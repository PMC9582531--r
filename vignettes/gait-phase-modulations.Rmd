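---
title: "Gait-phase related EEG power modulations: models, parameters and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Gait-phase related EEG power modulations}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The problem

Walking rhythmically modulates cortical oscillations. When EEG is recorded
during overground walking, band power at central sensorimotor electrodes
rises and falls within each stride: theta and alpha/mu power tend to
increase around the double-support phases (both feet on the ground), beta
power decreases there and rebounds during single support. These *gait-phase
related power modulations* (GPMs) are a candidate readout of the cortical
cost of gait control: harder terrain or a concurrent task should change
them if gait demands more cortical involvement.

The obstacle is that walking EEG is drenched in artifact: neck and
shoulder EMG bursts time-locked to the very gait phases under study, cable
and electrode motion, mains interference, blinks. A pipeline that claims a
condition difference in GPMs must therefore (a) detect gait events without
optical motion capture, (b) attenuate artifacts without touching the
condition contrast, and (c) quantify how much artifact is left.
`gaitGPM` implements that pipeline end to end, together with a synthetic
data generator that knows the ground truth, so every stage is testable
without any recordings.

## The analysis model

**Gait events from foot accelerometry.** Each foot carries a 3D
accelerometer (250 Hz, units g). Per foot, the signal is linearly
detrended and low-pass filtered with a zero-phase 2nd-order Butterworth
design (forward-backward, hence effective order 4) at 30 Hz, plus an
interim 6 Hz version. Step markers are peaks of the 6 Hz vertical axis
exceeding 0.6 g (fallback 0.24 g) at least 500 ms apart — roughly
mid-swing. The heel strike is the first 30 Hz vertical peak above 0.6 g
after a marker; the toe-off is the mean latency of the two highest
anterior-posterior peaks above 0.2 g in the 500 ms before a marker. A
candidate gait cycle spans consecutive right heel strikes (RHS) and is kept
only when the event order is RHS < left toe-off < left heel strike < right
toe-off < next RHS and the duration lies in [0.5, 1.5] s. Stride time is
the RHS-to-RHS duration; stride-time variability is the coefficient of
variation, `100 * sd / mean` with the sample SD.

**EEG cleaning.** The chain is: downsample to 250 Hz; zero-phase FIR
band-pass 0.2–60 Hz (a long high-pass with a 0.2 Hz transition convolved
with a short low-pass); bad-channel detection (flatline ≥ 5 s, spline-
prediction correlation < 0.8, line-noise ratio z > 4); a burst-correction
hook with the calibration contract of artifact subspace reconstruction
(standing baseline, cutoff 20 SD) whose internals are out of scope — the
default pipeline substitutes epoch rejection; sliding-window sinusoid
regression at 50 Hz; spherical-spline interpolation of the flagged
channels; full-rank common average reference (the online reference FCz is
reconstructed as a zero channel before averaging, so no rank is lost);
and ICA eye-artifact removal. The ICA is a fixed-seed symmetric FastICA
with PCA whitening at numerical rank, fitted on a 1 Hz high-passed copy
restricted to clean 1 s epochs (350 µV absolute gate plus a
joint-probability criterion: per-channel epoch log-likelihood under a
kernel density estimate, robust z < −3) and back-projected to the full
recording. Components are scored for eye-likeness by a documented
heuristic — frontal concentration of squared mixing weights (relative to a
uniform topography, calibration constant 3) times the sub-3 Hz power
fraction of the source (calibration constant 0.5), both clipped at 1 — and
removed above 0.90. The heuristic stands in for a trained classifier and is
swappable (`scorer` argument).

**Time-frequency decomposition and warping.** Morlet wavelets on a linear
2–60 Hz grid in 2 Hz steps give power per channel, frequency and sample.
The quiet-standing segment, averaged over time with the same wavelets,
provides the baseline power. Each plausible gait cycle whose time-domain
amplitude never exceeds 350 µV is linearly resampled onto 100 phase bins
(bin 0 at RHS), cycles are averaged, and the gait ERSP is
`10·log10(mean cycle power / standing baseline)` in dB. The GPM subtracts,
per channel and frequency, the ERSP mean across the 100 bins, leaving
pure within-cycle modulation (every row is exactly zero-mean).

**Spectral PCA (sPCA).** Muscle artifact in walking EEG shares one
broadband spectral signature whose variance dwarfs the narrowband neural
modulations. Treating each (channel, phase-bin) pair of the subject's
all-condition average ERSP as an observation over the 30 frequency
variables, a mean-centred PCA is fitted and exactly the first component
removed; the resulting projector (symmetric, idempotent) is applied
unchanged to every condition-specific ERSP of that subject, so the
attenuation cannot manufacture condition differences.

**Data-quality footprint.** Five features, each oriented so larger = more
artifact: B, the variance share of the first spectral PC; C, mean
positive-dB ERSP over lateral versus medial channels; D, the same for neck
versus all non-neck channels; E, mean |GPM| in double- versus
single-support bins (support bins derived from each recording's own mean
event timing); F, the mean linear walking/standing power ratio. Cleaning
success is the Euclidean distance between the pre- and post-cleaning
feature vectors after min–max scaling each feature to [0, 1] over the
cohort (both states pooled). The absolute distance depends on that scaling
choice and is not comparable across cohorts.

**Statistics.** Stride time and CV enter 2×2 repeated-measures ANOVAs
(terrain × task); for a 2×2 within-subject design every effect reduces to
a paired t on the corresponding contrast, with F = t², df (1, n−1) and
partial η² = F/(F + n − 1) — the implementation is tested against a
brute-force `aov()` error-stratum oracle. Ordinal or non-normal paired
data use the Wilcoxon signed-rank test with the matched rank-biserial
correlation R; effect sizes for t-tests are paired Cohen's d (dz = t/√n);
multiplicity uses Bonferroni–Holm. GPMs at the analysis channel (Cz by
default), 6–40 Hz × 100 bins, are compared with three cluster-based
dependent-samples permutation tests — terrain and task as main-effect
averages, the interaction as the paired difference of task contrasts
between terrains. Bins with |t| above the two-tailed critical value at
α = 0.05 form 4-connected same-sign clusters; cluster mass is the summed
t; the null is the maximum |mass| under per-subject sign flips
(default 1000); p = (1 + #{null ≥ observed})/(n_perm + 1). Significant
clusters get a paired dz computed from each subject's mean difference over
the cluster bins.

## The synthetic world

`study_spec()` states the world the generator emulates; these defaults are
fixed, not tuned:

* **Stride timing.** Mean stride times 1.05/1.10/1.15/1.20 s for
  even-ST/even-DT/uneven-ST/uneven-DT, within-subject SDs 0.025 s (even)
  and 0.045 s (uneven), between-subject intercept SD 0.05 s. The source
  study reports only effects, not per-condition means; these values encode
  its qualitative pattern — slower strides on uneven terrain and under
  dual-tasking, more variable strides on uneven terrain only, no
  interaction — at magnitudes typical of healthy young adults.
* **Accelerometry.** Per stride: a broad vertical mid-swing bump (1.2 g,
  SD 50 ms) that survives the 6 Hz filter; a sharp heel-strike transient
  (0.9 g, SD 12 ms) visible at 30 Hz but strongly attenuated at 6 Hz; two
  anterior-posterior bumps (0.50/0.45 g) placed ±40 ms around the true
  toe-off so the mean of the two peak latencies is exact. Additive
  Gaussian noise, default SD 0.05 g. Waveform shapes are free choices;
  only detectability under the stated rules is contractual.
* **EEG.** A 1/f background built from pink-noise sources with smooth
  random scalp topographies (width 1.1 on the unit sphere) mixed to equal
  channel power, plus 1.5 µV white sensor noise — real EEG is spatially
  predictable, and the bad-channel correlation rule (floor 0.8) depends on
  that. Band oscillations (theta 7 Hz at Fz, alpha 12 Hz and beta 25 Hz at
  Cz, 20 µV at their centres) carry two-peaked cosine power profiles over
  the cycle (peaks at the double-support phases, 0–15% and 50–65%), with
  per-band peak-to-trough depths of 1.5/1.5/2 dB and subject noise SD
  0.8 dB. The condition effect is a localized Gaussian "dip": 1 dB of
  extra beta power decrease centred at 7.5% of the cycle (SD 5.5%) on
  uneven terrain only, subject SD 0.8 dB — a design-level paired dz of
  about 1.25 concentrated at 18–34 Hz and 2–15% of the cycle, which is
  what the statistics should (and do) find, with no task effect and no
  interaction by construction.
* **Artifacts.** EMG-like bursts from four shared pink-spectrum sources
  over the neck + lateral channel set (base 3 µV RMS, amplitude gain 6 dB
  inside a smoothed double-support envelope, walking only); a 50 Hz mains
  sinusoid (2 µV, ±20% per channel); stereotyped 120 µV, 0.3 s blink
  bumps with a frontally concentrated topography at 0.2 Hz.
* **Standing baseline.** 120 s by default. The source protocol states
  2 min outdoors while the decomposition section says 4 min; the duration
  is a parameter and the discrepancy is documented rather than resolved.

What a green test does *not* establish: the generator has no biomechanical
realism beyond detectability (no gyroscope physics, no spatial gait
parameters), no non-stationary artifact epochs of the kind ASR targets, no
realistic EMG spectrum (pink by construction so that channel-level spectral
criteria stay comparable across the scalp), and no eye movements beyond the
stereotyped blink template. Results on real recordings depend on those
phenomena too.

## Numerical choices and edge cases

* Zero-phase IIR filtering uses odd-reflection padding of
  `max(9, 3·fs/fc)` samples; FIR filtering is FFT-based with the group
  delay compensated exactly, and high-pass orders follow the
  3.3/transition-width Hamming rule.
* Peak finding breaks minimum-distance conflicts greedily by descending
  height. The heel-strike search starts 60 ms after the step marker so the
  marker's own 30 Hz peak cannot be taken for a heel strike (mid-swing and
  heel strike are at least ~85 ms apart for any plausible stride).
* Wavelet widths are unspecified in the source; the default rises linearly
  from 3 cycles at 2 Hz to 8 at 60 Hz, exposed in `tf_params()`. Edge
  samples within 3 temporal SDs of either end are excluded from baseline
  averaging. Warping interpolates the power envelope, not the raw signal.
* The cycle gate (350 µV) is applied to the cleaned time-domain signal of
  any channel; excluded cycles are counted so the bookkeeping identity
  `kept = valid − excluded` always holds.
* The epoch joint-probability criterion rejects only the low-likelihood
  tail (improbable epochs); a two-sided rule would discard ~9% of perfectly
  Gaussian data at 3 SD across 32 channels.
* `fit_spca()` centres the frequency variables before the PCA (the origin
  method leaves this implicit) and pools channels into one projector per
  subject; a per-channel variant can be obtained by fitting per channel.
* The cluster phase axis is non-circular by default (`circular = TRUE`
  available); permutation p-values use the add-one estimator, so the
  smallest attainable p is 1/(n_perm + 1).
* Degenerate inputs are flagged, not silently absorbed: zero-SD paired
  differences give an infinite, `degenerate`-flagged d; a single valid
  cycle gives a defined mean but `NA` CV; an all-zero standing baseline is
  an error because dB is undefined.

## Scaled-down profile

The full chain on a 19-subject study is minutes of FFTs. For recovery
experiments that only need the phase-locked statistics at the analysis
channel, `pipeline_config(profile = "minimal", tf_channels = ...)` runs:
resample → full-rank CAR → channel subset → light band-pass (0.5 Hz
transitions). Common-average referencing and linear filtering commute, so
subsetting after CAR is exact. This profile skips bad-channel handling,
line removal, ICA and sPCA — each of which is unit-tested in isolation —
and is what the end-to-end acceptance test uses (60 s bouts, 8-channel
montage, 6–40 Hz grid, 500 permutations), trading per-subject estimation
noise against runtime while leaving the stated between-subject effect
(dz ≈ 1.2) untouched.

## Known limitations

* The ASR stage is a hook with a calibration contract, not an
  implementation; AMICA and the trained component classifier are replaced
  by documented stand-ins. Claims about those specific algorithms cannot
  be tested here.
* The idealised montage is a spherical layout with standard labels, not a
  digitised cap; spherical-spline interpolation quality at the lowest row
  is correspondingly approximate.
* Footprint distances depend on the cohort min–max scaling; only
  within-cohort comparisons (e.g. cleaned versus raw, sign tests across
  subjects) are meaningful.
* Footprint feature B is non-monotone under sPCA when the artifact is only
  moderately dominant: removing a component carrying, say, 40% of the
  spectral variance renormalises the remaining low-rank neural structure,
  whose new first-component share can exceed the old one. The
  "all features decrease after cleaning" property holds in the
  artifact-dominated regime the footprint was designed for (first-PC share
  well above one half), which is how the acceptance fixture is configured
  (12 dB bursts); with 6 dB bursts B can tick upward while C–F still fall.
* Exact reproduction of published cluster boundaries is out of reach by
  design: the cluster-forming threshold and permutation count of the
  original analysis are unreported, and permutation clusters do not
  license location inference in any case.
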