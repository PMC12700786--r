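---
title: "Thalamo-cortical phase synchronisation: models, parameters and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Thalamo-cortical phase synchronisation: models, parameters and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

This vignette is the package's account of its science: the measures it
computes, the statistical machinery behind them, what the synthetic
cohort generator does and does not emulate, and the choices made where
the design was genuinely open. Nothing here states an empirical result
that the test suite or `scripts/acceptance.R` does not itself compute.

## The setting

A patient with a sensing-enabled DBS implant in the medial thalamus
(CM-Voi or VA/VL target) provides two simultaneous recordings: a
bipolar thalamic local field potential per hemisphere, streamed at
250 Hz by the pulse generator, and 63-channel scalp EEG at 5000 Hz.
Stimulation is off. The two streams run on independent clocks and are
aligned offline through stimulation artifacts induced at the start and
end of each streaming; `synchronize_streams()` fits
`b = offset + (1 + drift) * a` to the matched artifact times by least
squares and all events are kept on a single session clock.

Three epoch types drive the analyses:

* **rest epochs** — non-overlapping 4-s segments fully outside every
  tic, movement and artifact event (1-s guard margin), tiled greedily
  left to right;
* **tic epochs** — one trial per isolated tic, anchored at onset,
  window −2.1 to 0.9 s (the −1.8 to 0.6 s analysis range padded by
  0.3 s so that 0.3-s sliding windows never run out of samples);
* **suppression epochs** — rest-like segments from the tic-suppression
  condition.

Tic bookkeeping follows two rules applied in order: tics separated by
less than 2 s merge into a single sequence spanning first start to last
end (`merge_tic_sequences()`), and only tics preceded by at least 2 s
of tic-free time are analysed (`select_isolated_tics()`). "At least
2 s" is read inclusively: a preceding offset exactly 2.0 s before the
onset keeps the tic.

## Spectral decomposition and the PSI

`decompose()` convolves every trial and channel with complex Morlet
wavelets — 5 cycles, 1-Hz grid over 2–40 Hz by default. Two numerical
choices matter:

* kernels are **L2-normalised per frequency**, so broadband noise
  contributes equal expected power to every bin (the absolute scale is
  arbitrary and cancels in normalised spectra and in all phase
  measures);
* epochs are **mirror-padded** beyond both edges before the FFT
  convolution, and samples closer than two wavelet standard deviations
  to an edge are flagged; static averages exclude flagged samples,
  sliding series retain them (the tic-epoch padding keeps the analysis
  range clean).

Power spectra are normalised per channel to percent of total 2–40 Hz
power, which makes them gain-invariant and comparable across patients.
Band values are unweighted means over the grid frequencies inside
theta = 3–7, alpha = 8–12, beta = 13–30 Hz, bounds inclusive.

The phase synchronisation index is implemented as the phase-locking
value: the modulus of the mean unit phasor of the phase difference over
all trials and valid samples, per frequency, then band-averaged. This
is one of the two standard readings of "PSI" (one phase estimate per
sample and trial, versus one per trial); the sample-and-trial mean is
used because it is the stabler estimator at the study's trial counts.
Surrogates permute the trial pairing between the two channels
(non-identity permutations only) and average the recomputed PSI over
100 iterations; trial-pairing shuffles preserve the within-trial
spectral structure and the trial count, which the original-vs-surrogate
ANOVA needs matched. The expected resultant of N uncoupled unit
phasors, sqrt(pi)/2/sqrt(N), is the chance level the suite checks the
surrogate against.

## The permutation inference engine

Every test derives its p-value from shuffled data, never from a
parametric reference distribution; a Shapiro-Wilk diagnostic
(`shapiro_gate()`) is reported but never switches the inference path.
Conventions shared by all tests:

* two-sided throughout; the observed labelling is counted into the
  null, so `p >= 1/(n_permutations + 1)` and p can never be exactly 0;
* paired t-tests build the null by random sign flips of the within-pair
  differences; zero-variance differences return p = 1, flagged;
* the ANOVA uses Type II sums of squares (robust to hemisphere
  imbalance, textbook decomposition when balanced; the observed F is
  cross-checked against an independent Type II implementation in the
  tests) and permutes only the tested factor's labels — for an
  interaction, the first factor's labels within the cells of the other
  factors in that interaction;
* Spearman's rho uses average ranks; for n <= 8 the p-value is exact by
  full enumeration of all n! orderings (a multiple of 1/n!), otherwise
  Monte-Carlo;
* cluster correction binarizes the window p-series at alpha = 0.05,
  measures clusters by run length (size, not mass), shuffles the
  binarized sequence 10000 times and keeps clusters longer than the
  99.9th percentile of the null maxima (quantile type 1, strict
  inequality). Shuffling the binarized series rather than recomputing
  statistics under permutation is deliberately conservative — and has
  the curious edge case that an entirely significant series can never
  be flagged, since it is shuffle-invariant;
* adjusted R² is reported for trend regressions,
  `1 - (1 - R²)(n - 1)/(n - 2)`; only an adjusted statistic can print
  as "−0.00" when F = 0.

## The synthetic cohort generator

`generate_recording()` builds, per patient:

* a common **alpha oscillator**: instantaneous frequency meandering
  inside `band_center ± band_width/2` (default 10 ± 1 Hz) between
  0.5-s interpolation knots;
* two LFP channels carrying the oscillator plus 1/f background noise
  (spectral shaping of white noise);
* EEG channels `cos(phase + theta_c(t))` plus their own 1/f noise,
  where `theta_c` is von Mises phase jitter with channel-specific
  concentration kappa, piecewise constant over 2-s blocks. Piecewise
  constancy is what makes the measured PSI converge to the closed-form
  von Mises resultant I1(kappa)/I0(kappa) — the generator's central
  oracle — because the wavelet phase estimator cannot average away
  jitter that is constant on its integration timescale. Channels with
  kappa ≈ 0 instead carry an **independent** oscillator: an uncoupled
  channel's alpha is its own, and modelling it as the common oscillator
  with scrambled offsets would bias its original PSI above the
  surrogate level;
* a **pre-tic decoupling ramp**: inside `[ramp_start, 0]` before each
  tic the jitter blocks shrink to 150 ms (the alpha wavelet's
  integration timescale — shorter blocks are smoothed away by the
  phase estimator) and the effective kappa falls linearly to
  `kappa * (1 - ramp_depth)` at onset; the floor holds through the tic
  before recovering;
* sync artifacts near both ends, tic events with the isolation
  structure the epoching rules expect.

Key parameters, defaults, and why:

| parameter | default | rationale |
|---|---|---|
| `kappa_range` | 2–30 | per-patient coupling; PLV 0.70–0.99, strong enough that every pipeline stage has signal to recover |
| `snr` | 10 | oscillation RMS over 8–12 Hz background RMS; keeps measurement phase noise well below the von Mises jitter so the Bessel-ratio oracle holds within its 0.03 tolerance |
| `band_center`, `band_width` | 10, 2 Hz | a narrowband resting alpha peak |
| `ramp_start`, `ramp_depth` | −0.3 s, 0.8 | pre-onset decoupling window and its depth |
| clinical link | ygtss = 420 − 410·PLV, puts = 460 − 435·PLV, noise SD 2 | maps the default PLV range onto severity ranges typical of medicated adult TS cohorts (YGTSS TTS ≈ 10–35, PUTS ≈ 20–50); monotone negative, so the pipeline should recover a negative PSI–severity correlation |
| `eeg_rate`, `lfp_rate`, `duration` | 5000, 250, 420 s | the recording contract of the emulated setting |

What the generator does **not** emulate: volume conduction and sensor
mixing (each channel couples independently), ocular/muscle/movement
artifacts, the EEG cleaning that real data would need, non-stationary
background spectra, cross-frequency structure, and genuinely
band-limited power modulations around tics. Passing recovery tests
therefore demonstrates that the pipeline's statistics recover the
programmed structure from realistic signal-to-noise time series — not
that the pipeline is robust to every pathology of real scalp data.

## Pipeline-level choices

* **Units.** Each implanted thalamus is one independent sample for
  t-tests and ANOVA; patients are the unit for clinical correlations,
  computed on hemisphere-averaged values.
* **Rest ANOVA.** Per EEG channel: Condition (original vs surrogate) ×
  Frequency (theta/alpha/beta) × Hemisphere, followed by per-band
  original-vs-surrogate post-hoc comparisons; one FDR family across all
  channels' interaction p-values and all post-hoc p-values.
* **Spectral-specificity flag.** A channel is flagged when its
  interaction survives FDR and its alpha post-hoc difference is
  significant *and the largest across bands*. Strict "alpha and nothing
  else" exclusivity is also computed (`alpha_exclusive`) but is not the
  flag criterion: at strong coupling the 5-cycle wavelet's skirt leaks
  genuine alpha coupling into the 13–16 Hz bins, so a beta-band
  difference is real and detectable whenever the alpha effect is large;
  dominance, not exclusivity, is the scale-invariant reading of
  spectral specificity.
* **Sliding-window tests.** Test windows of 0.1 s step at 0.02 s from
  −1.8 s; the last window starts at 0.5 s, giving 116 windows over
  −1.8–0.6 s. Window values are means of the sliding series values
  whose centres fall in [t, t + 0.1). The rest comparator per
  hemisphere is the static rest PSI over a bootstrap sample of rest
  trials matched to the tic trial count, which equalises the
  trial-count component of the PLV estimator bias (the window-length
  component — 0.3 s windows versus 4-s epochs — remains, and is a known
  source of a small positive offset of the sliding series).
* **Pre-onset trend.** Fitted on the relative-change series at the full
  0.004-s grid over [−1.8, 0]: 451 points, so the regression df are
  (1, 449). These points are strongly autocorrelated (the sliding
  windows overlap heavily), so trend R² values are descriptive of the
  series shape rather than of independent evidence; the suite treats
  them accordingly.
* **Source stage.** Region-of-interest time series are consumed as a
  SOURCE-modality recording and flow through the identical PSI/power
  machinery; no inverse modelling is performed.

## Problem sizes used by the tests and scripts

The generator's defaults describe the emulated recording setting; the
test suite and the analysis scripts run a scaled version of it so that
the full pipeline — including 20-replicate recovery checks — completes
comfortably on one CPU: 6 patients, 120-s sessions, a 10-channel
montage (5 coupled frontal, 5 uncoupled) generated directly on the
250-Hz time base, 8 tics per patient, three grid frequencies per band,
50 surrogate iterations, and 300–2000 permutation iterations depending
on the test. The statistical structure (coupling range, clinical link,
ramp, isolation rules, window grids, hemisphere-as-sample convention)
is identical to the full-size setting. Calibration checks that need
their nominal sizes keep them: the type-I calibration uses 1000 null
datasets with 2000 permutations each, the Bessel-ratio oracle uses 200
rest epochs (Monte-Carlo tolerance 0.03), and the cluster
false-positive check uses 500 null series of length 116 with the full
10000-shuffle null.

## Known limitations

* The decoupling ramp redraws phases in short blocks; a phase jump also
  spreads energy out of the alpha band, so tic-locked *power* at coupled
  channels shows a genuine (generated) dip around onset even though no
  amplitude modulation is programmed. Thalamic LFP power carries no
  such artifact.
* BH-FDR admits on the order of q × (number of discoveries) false
  positives per cohort; with ~20 strong frontal discoveries, an
  occasional weak non-frontal flag is expected behaviour, which is why
  topography recovery is asserted as "frontal channels flagged and
  top-ranked", not "no other channel ever flagged".
* Both hemispheres share one oscillator, so the two hemisphere samples
  of the same channel are more correlated than real left/right
  thalamic signals would be; label-shuffling inference is slightly
  anticonservative in that respect.
* The averaged surrogate has a much smaller sampling variance than the
  original PSI, a heteroskedasticity the label-shuffling ANOVA does not
  model; this is inherent to using the surrogate ensemble mean.
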