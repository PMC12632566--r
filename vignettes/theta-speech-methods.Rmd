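---
title: "Sensorimotor theta and speech movements: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Sensorimotor theta and speech movements: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(thetaspeech)
```

## The scientific problem

Fluent speech requires motor commands timed at the scale of tens of
milliseconds, coordinating many articulators at once. A body of
intracranial work points to a 6–10 Hz "sensorimotor theta" rhythm in the
field potentials of ventral sensorimotor cortex (vSMC) as a candidate
timing scaffold: its frequency is stable across speaking rates, its phase
is coherent across speech-production sites, population activity (indexed
by high-gamma amplitude, 70–150 Hz) is maximal near theta troughs, and
vocal-tract velocity pulses — the kinematic signature of constriction
gestures — occur at a consistent, late theta phase, about a quarter cycle
after the high-gamma peak.

`thetaspeech` implements the full analysis chain needed to test these
claims, together with a synthetic-session generator that produces
recordings with exactly this statistical structure. Every downstream
stage can therefore be validated by parameter recovery: inject a known
rhythm, coupling phase, or gradient, and check that the estimators return
it.

## The synthetic session generator

`session_config()` + `make_session()` produce a complete session: a
multichannel field-potential recording, six tract-variable kinematic
trajectories at 100 Hz, and a tiered annotation table (utterances,
syllables with nucleus times, phonemes, fluency flags).

**Theta oscillator.** The carrier is frequency-domain shaped Gaussian
noise: complex white noise weighted by a Gaussian amplitude envelope
centred on `theta_f0` (default 8.2 Hz) whose power full-width at half
maximum is `theta_bandwidth` (default 1.5 Hz). Bandwidth zero degenerates
to a pure sinusoid. Smaller bandwidth means slower phase diffusion and a
larger secondary autocorrelation peak, which is the periodicity statistic
used in the rate analyses. This is the simplest stationary process that
matches a narrow spectral bump over a 1/f background; it does not model
cycle-amplitude asymmetries or burst-like rhythms.

**Channels.** Electrodes lie on a dorsoventral strip (z from 0 to
40 mm). Each channel's theta is the common carrier rotated by a phase
offset: a gradient of up to ~40 degrees along the strip, plus an
`antiphase_fraction` of dorsal channels at 180 degrees (default 0.2).
Inter-site locking to the common carrier is confined to utterances,
beginning `lock_preroll_s` (0.2 s) before onset; outside speech each
channel follows an independent carrier of the same frequency, so phase
coherence rises with speech while theta power does not. The background is
1/f^chi noise (chi = 1.5) and high-gamma is band-limited noise whose
envelope is `1 + pac_depth * cos(theta - pac_phase)`, gated up during
speech.

**Coupling phases.** The defaults place high-gamma at 208 degrees (near
the trough at 180) and articulatory-change pulses at 301 degrees, so the
injected AC-versus-high-gamma offset is 93 degrees — the ordering the
pipeline is designed to measure. Placing high-gamma exactly at the trough
would make that offset 121 degrees, which is inconsistent with the
quarter-cycle separation; "near the trough" is the model.

**Kinematics.** Within utterances, every theta cycle carries a gesture at
the preferred phase, skipped independently with `cycle_skip_prob`
(default 0.11, so the fluent pulse rate is 8.2 x 0.89 ~ 7.3 pulses/s).
Each gesture is a Gaussian velocity bump (sigma = 20 ms) in 2–4 randomly
chosen tract variables, normalised by synergy size; positions are
trapezoidal integrals of velocity (rectangle-rule integration would shift
every pulse by half a sample, a 15-degree phase bias at 8.2 Hz). Gestures
nearest a planned vowel nucleus are larger (amplitude 1.5) than the
flanking consonant gestures (1.1) and fillers (1.0), matching the roughly
2:1 vowel-to-consonant pulse ratio of articulographic recordings.
Syllable nuclei are planned at `syllable_rate` with ±25% duration jitter
(natural speech is not isochronous), then snapped to the realised
theta-locked pulses; annotations record the realised times, as acoustic
segmentation of produced speech would.

**Error trials.** A fraction of utterances is flagged as error/repair
trials. On those, gesture times receive Gaussian phase jitter
(`error_phase_jitter_sd`, default 60 degrees) *and* the channels do not
lock to the common carrier. The second ingredient matters: it models a
breakdown of coordination with unchanged oscillatory power, and it is
what lets the across-electrode dispersion of preferred phases grow on
error trials. If error trials only jittered the common rhythm, every
electrode would deviate identically and the dispersion contrast could
never appear.

**What the generator does not emulate.** Volume conduction, electrode
noise heterogeneity, realistic phonetics beyond consonant–vowel timing,
acoustic output, non-stationary theta frequency drift, and amplitude
asymmetries of real rhythms. Passing recovery tests on these sessions
shows the estimators are correct and calibrated under the stated model;
it does not certify behaviour under artefacts the model lacks.

## Spectral analysis

`welch_psd()` averages Hann-tapered modified periodograms (2-s segments,
50% overlap by default, giving 0.5 Hz resolution; the one-sided density
integrates to the variance). `detect_spectral_peak()` implements the
screening rule: remove a robust log–log linear trend, z-score the
residual, and require a local maximum of prominence above 3 SD.

`parameterize_spectrum()` separates aperiodic and periodic components.
The aperiodic line is fitted by iteratively trimming strong positive
outliers (peak bins) so that peak-free spectra are not biased low; if the
resulting exponent is implausible (outside [-1, 5]) the line falls back
to the floor bins, which guards against tracking the skirt of a dominant
peak when no true 1/f background exists. Peaks are detected on a lightly
smoothed version of the log residual (single-bin periodogram fluctuations
are not peaks, and a minimum height of 0.1 log10 units applies), but
their centre and width are *moments of the background-subtracted linear
power* in a local window. This departs from fitting Gaussians in log
power, deliberately: a symmetric additive spectral bump is skewed in log
space wherever it meets the sloping background, which biases fitted
centres upward by 0.1–0.4 Hz for peaks of realistic size. Linear-power
moments recover injected centres to better than 0.15 Hz on 60-s sessions
and preserve the monotone bandwidth–width relationship.

`peri_event_spectrogram()` uses 6-cycle Morlet wavelets with either
relative normalisation (each time column sums to one) or baseline
normalisation (dB versus the pre-speech interval).

## Phase coherence

`band_analytic()` band-passes with a zero-phase frequency-domain filter
(raised-cosine transitions; the input is detrended first because FFT
filtering assumes periodicity) and takes the analytic signal. The phase
convention everywhere is 0 at the waveform positive peak and pi at the
trough.

`sliding_plv_coherogram()` computes, per window and frequency, the mean
resultant length of instantaneous phase differences (0.5-s windows,
0.05-s steps), averaged over event-locked epochs. For narrowband rhythms
this within-window estimator has a high floor — two independent
oscillators at the same frequency drift apart only slowly within half a
second — so the meaningful quantity is the change against the pre-event
baseline. The `across_trials` estimator (resultant length of the phase
difference across trials per time point) has a much lower floor
(~1/sqrt(trials)) and is the better choice for event-locked designs; both
are provided because the within-window form matches sliding-window
displays. The default frequency grid starts at 4 Hz so every window holds
at least two cycles; a longer window restores the 3 Hz floor.

`coherence_change_stats()` subtracts each pair's baseline, averages pairs
within subject, runs a one-sample t-test across subjects per
time–frequency cell, and controls FDR by Benjamini–Hochberg. A caveat
shown by the synthetic sessions: if locking begins before the event, the
default [-1, 0] baseline is partially contaminated, which produces small
*negative* significant cells before onset; the preparatory rise is the
first significant cell with positive effect.

`phase_offset_map()` reports per-channel circular-mean offsets relative
to a reference site over speech samples, classifies them (near-zero
within 45 degrees, antiphase within 45 degrees of 180), and flags
channels within 15 mm of the reference as excluded.

## Coupling

`tort_mi()` bins phase into 24 bins of 15 degrees, averages the magnitude
per bin, normalises the profile to sum to one, and reports the
Kullback–Leibler divergence from uniformity divided by log(24), so the
modulation index (MI) lies in [0, 1]. The same 24-bin profile serves both
high-gamma amplitude and articulatory change; `preferred_phase()` is the
profile-weighted circular mean.

`circular_shift_surrogates()` (and the `phase_coupling()` wrapper, which
applies shifts before any sample mask so surrogates keep their
autocorrelation) draws shifts uniformly outside ±1 s and uses the add-one
permutation p-value, whose minimum is 1/(n+1). One practical point the
tests encode: surrogate inference is only meaningful for a *stochastic*
phase series — circularly shifting a strictly periodic phase by a
multiple of its period reproduces the original alignment exactly.

## Kinematics and encoding models

`articulatory_change()` low-passes the trajectories at 20 Hz,
differentiates by central differences, sums squared velocities across
tract variables, and smooths with a 15-ms Gaussian. The 20 Hz / 15 ms
pair was chosen because the articulatory pulse train itself lives at
7–9 Hz: a 10-Hz trajectory low-pass with 25-ms smoothing (an earlier
candidate) merges roughly one pulse in ten into its neighbour at fast
rates, which destroys rate estimation. `ac_pulse_analysis()` detects
local maxima above the within-utterance median (a scale-free threshold
that sits between pulse peaks and valleys at these duty cycles; a
median-plus-MAD rule rejects half of the genuine pulses) with 60-ms
minimum separation, and reports inter-peak intervals and the median
per-utterance rate.

`fit_mtrf()` is a lag-expanded ridge regression (lags -0.6 to +0.6 s,
penalty chosen by blocked 5-fold cross-validated R-squared from a
10^-2..10^6 grid). `unique_variance()` is the cross-validated R-squared
drop from ablating one feature under the same protocol.
`trf_response_profile()` returns a feature's weight-versus-lag curve with
annotated peaks. Two modelling notes from the synthetic sessions: the
*vowel-only* kernel shows the syllable triplet (nucleus pulse flanked by
consonant gestures one theta cycle away) because regression deconvolves
the vowel train's own autocorrelation, removing neighbouring vowels; and
in the two-feature model the consonant kernel is single-peaked because
the vowel regressor explains the flanking vowel pulses. Raw peri-event
averages (`peri_event_profile()`) show the full cycle comb instead.

## Phase warping and decoding

`locate_anchor_trough()` finds the trough (phase pi) nearest an anchor,
ties broken toward the earlier one. `phase_warp_epochs()` re-references
each trial's unwrapped phase so the anchor trough maps to 0 and linearly
interpolates all signals onto a common axis spanning [-9 pi, 7 pi] with
160 points (ten per half cycle); trials are never extrapolated, short
non-monotonic phase slips are repaired by a running maximum, and slips
longer than 50 ms drop the trial. On a constant-frequency rhythm warping
is exactly uniform time resampling, which the tests assert to 1e-6.

`phase_locked_average()` averages a warped signal across trials and
builds a null band from 50 per-trial circular shifts along the phase axis
(equivalent to shifting each trial's theta phases and re-warping); it
also returns the normalised histogram of per-trial peak phases.

`sliding_phase_decoder()` trains a linear one-versus-rest SVM on
high-gamma features averaged within a 0.3-radian sliding window
(features z-scored inside training folds; stratified 5-fold
cross-validation; classes under 10 repetitions dropped). The per-bin null
permutes labels against the stored cross-validated predictions — for
balanced classes its mean is exactly 1/K — and repeated shuffles give an
add-one p-value, FDR-controlled across bins. Retraining per shuffle is
available (`refit = TRUE`) but changes none of the calibration
properties. The SVM cost defaults to 1; passing a grid enables nested
3-fold selection. `combine_significant_bins()` sums per-trial class
scores over significant bins weighted by bin accuracy and takes the
arg-max.

## Sequence statistics

`xcorr_latency()` takes the peak of the normalised cross-correlogram
(±300 ms) between an electrode's peri-AC activation profile and the
grand-average profile; ties go to the smallest absolute lag.
`circ_linear_corr()` is the multiple correlation of the linear variable
on (cos, sin) with both a permutation and an asymptotic chi-squared
p-value. `pairwise_lag_phase_corr()` correlates latency differences with
wrapped phase differences over all unordered pairs; because pairs share
electrodes, significance comes from permuting electrode labels. The
phase entering `latency_phase_table()` is the electrode's *lag* relative
to the ventral reference (positive = running behind); under this
convention the injected dorsoventral gradient yields the positive
latency–phase correlation, while the opposite sign convention flips r
without changing magnitude or significance.
`activation_state_space()` projects electrode-by-lag profiles onto the
first two principal components and reports, per lag, the circular mean
phase of the most active tenth of electrodes (`round(0.1 * n)`).

## Rhythm, rate, and fluency

`acf_periodicity()` band-filters, computes the autocorrelation with
unbiased normalisation (so a pure sinusoid's secondary peak is 1), and
takes the first local maximum beyond half a cycle.
`rate_periodicity_analysis()` median-splits subjects by syllable rate
(stable order on ties, flagged) and reports a rank-sum comparison plus
the Spearman correlation. `matched_trial_resample()` draws fluent control
sets matched to the error trials by nearest-neighbour matching on
standardised syllable rate and duration, without replacement within a
resample, 200 times. `fluency_coupling_contrast()` computes per-electrode
MI and preferred phase per group, tests the MI reduction by paired
one-sided Wilcoxon across electrodes, and compares the across-electrode
consistency of preferred-phase differences (fluent odd/even halves versus
fluent-versus-error) with a two-sample concentration test implemented as
a permutation on the difference of resultant lengths. `circ_tests()`
bundles the mean resultant length, the Rayleigh uniformity test (with the
standard finite-n correction), and the two-sample Watson U-squared test
with a permutation p-value. Conversational articulation rate
(`articulation_rate()`) counts syllables over voiced time, treating gaps
longer than 150 ms as pauses.

## Problem sizes and numerical choices

The test-suite and the acceptance script run on sessions of 40–160 s at
1 kHz with 4–24 channels, 200-run Monte-Carlo calibrations, 199–300
surrogates or shuffles per inference, and 20-seed recovery sweeps —
sizes at which every recovery band quoted above was measured. Key fixed
choices: Welch segments 2 s; Morlet 6 cycles; filter transition 1 Hz for
theta and 5 Hz for high-gamma; MI bins 24; minimum surrogate shift 1 s;
phase axis 160 points; SVM cost 1; ridge grid 10^-2..10^6; blocked
cross-validation to respect autocorrelation. Degenerate inputs error
early and explicitly (empty phase bins name the bin; uniform profiles
have no preferred phase; flat profiles have no latency).

## Known limitations

Group inference uses hierarchical aggregation (pair or electrode to
subject, then a one-sample test across subjects) rather than mixed-effects
models; with few subjects this is conservative and discrete. The
within-window coherence floor for narrowband signals means absolute
coherence values are not comparable across bandwidths — only
baseline-referenced changes are. The spectral peak moments assume an
approximately symmetric bump on a slowly varying background; heavily
overlapping peaks are merged by design (an overlap guard keeps the
taller). The generator's rigid theta locking makes some quantities
(realised pulse rate, warp-axis coverage) slightly seed-dependent through
cycle-skip draws and phase diffusion, which is why recovery tests quote
tolerance bands rather than exact values.
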