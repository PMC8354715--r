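---
title: "Methods: perturbational complexity and phase-locking analysis with percort"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: perturbational complexity and phase-locking analysis with percort}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The scientific problem

A single electrical pulse delivered to the cortex elicits an event-related
potential (ERP) whose spatiotemporal structure depends on brain state. In
wakefulness the response is long-lasting and differentiated: multiple cortical
areas produce distinct, phase-locked waveforms with sustained high-frequency
(HF, 20-40 Hz) activity. Under anesthetics that abolish consciousness-like
dynamics (propofol, sevoflurane) the same stimulus evokes a stereotyped slow
wave: after the initial activation the HF power collapses below baseline (an
"OFF period", the EEG signature of a neuronal down-state), the deterministic,
phase-locked part of the response ends early, and functional connectivity
between areas breaks down. Ketamine, which preserves dream-like experience,
sits in between. `percort` implements the quantitative pipeline behind these
observations for multichannel epidural EEG, together with a synthetic-session
generator that makes every stage testable against known ground truth.

The headline statistic is the state-transition perturbational complexity
index,

$$\mathrm{PCI^{ST}} = N_C \times \overline{\Delta \mathrm{NST}},$$

the product of the number of principal components of the evoked response that
survive dimensionality reduction and signal-to-noise gating ($N_C$, spatial
differentiation) and the mean number of significant state transitions per
component ($\Delta$NST, temporal complexity).

Phase-locking across trials is measured by intertrial phase clustering,

$$\mathrm{ITPC}_{tf} = \Bigl| n^{-1} \sum_{r=1}^{n} e^{i k_{tfr}} \Bigr|,$$

the modulus of the trial-mean unit phasor of the phase $k$ at a
time-frequency point ($1$ = perfect phase locking, $0$ = uniformly dispersed
phases). Connectivity uses the same construction on phase *differences*
between channel pairs (intersite phase clustering, ISPC), and the
connectivity degree (CD) of a channel is its fraction of significantly
ISPC-connected partners, normalized by channels $-$ 1.

## Pipeline and parameters

Preprocessing (`condition_signal`, `epoch_and_correct`,
`interpolate_stim_artifact`, `reject_trials`) follows the standard evoked
chain: common-average re-referencing for ERP analysis (a frontal-occipital
bipolar derivation for spontaneous activity), a zero-phase 3rd-order
Butterworth band-pass of 0.5-80 Hz, polyphase resampling to 500 samples/s,
cubic-spline interpolation of the stimulus artifact in 0-0.005 s (10 anchor
samples per side), epochs of -5 to 5 s, per-trial baseline (-1-0 s) offset
correction, and rejection of trials whose pooled baseline rms exceeds the
across-trial mean + 3 SD. Filtering is forward-backward so evoked latencies
are not shifted. All windows are closed on the left and open on the right on
the sample grid, with t = 0 the first response sample; frequency-band edges
are inclusive.

Time-frequency analysis (`morlet_tf`) uses 40 complex Morlet wavelets of 3
cycles each, linearly spanning 1-40 Hz, with the Gaussian envelope truncated
at ±4 SD, convolved over the full epoch so edge effects stay outside the
analysis windows. Per trial, channel and frequency the squared magnitude is
normalized by the trial-averaged baseline power (-0.5 to -0.2 s), averaged
over trials, and expressed in dB (`power_db`); this makes dB maps exactly
invariant to global signal rescaling. The coefficient grid retained for the
standard analyses is cropped to -0.6-0.85 s and decimated to 100 Hz: every
analysis window (baseline -0.5 to -0.2 s; OFF-period detection 0-0.3 s; HF
quantification 0.08-0.18 s; ITPC drop and late HF up to 0.8 s) lies inside
it, and 10 ms resolution is finer than every timing tolerance used.

### Bootstrap significance

The reference analysis retains only significant deviations from baseline
(power and ISPC: two-sided, $\alpha$ = 0.05; ITPC: one-sided increments,
$\alpha$ = 0.01; 500 permutations each), with non-significant values set to
exactly 0. The null construction is a baseline time-point bootstrap: per
permutation, one baseline time point is drawn per trial and the trial-mean
statistic recomputed — once for each of K = (number of baseline samples)
draws — and the permutation contributes its extremes over those K draws.
Thresholds are the $\alpha$-level percentiles of the extremes, per channel
and frequency. A point is therefore significant only when it exceeds what the
unperturbed baseline process produces *anywhere along a surrogate baseline
series*. This matters because the downstream summaries are extreme-value
statistics themselves: the ITPC drop is the *last* significant time point in
0-0.8 s and the OFF-period bounds are first/last zero crossings of the masked
dB series. Under a pointwise null calibrated per time sample, isolated false
positives among 40 frequencies x 80 time points would dominate those
summaries and make "last significant" drift toward the window end on any
input; against the baseline-extremes null the summaries are stable while
planted effects of a few dB (or locked phases) remain far above threshold.
The construction, level and seed are logged in each mask's `boot` field.

### OFF periods, late HF and the slow component

OFF-period detection (`detect_hf_suppression`) operates on the channel's
HF-band (20-40 Hz) mean of the masked dB series in 0-0.3 s: the start is the
time of the first sample below 0 dB (0 if the series starts negative), the
end the time of the first non-negative sample after the last suppressed one
(0.3 s if suppression persists), along with the minimum dB and its latency
and the mean HF dB in the fixed 0.08-0.18 s window. Zero crossings are
located by sign change between adjacent samples without sub-sample
interpolation. Late HF activations are positive significant HF-band values
in 0.08-0.8 s, summarized per channel (earliest onset) and as the fraction
of channels with any. The slow component (`slow_component`) is the < 4 Hz
zero-phase-filtered response, quantified by spontaneous (-2-0 s) and evoked
(0-0.3 s) rms and by the maximal absolute peak of the ensemble average
(SC max) in 0-0.6 s.

### Phase-locking duration and connectivity

The ITPC drop (`drop_times`) is, per channel, the last time in 0-0.8 s at
which the masked 8-40 Hz band-mean ITPC is nonzero, with strict "last"
semantics (no gap tolerance), a censoring flag when significance persists to
the window end, and 0 with a flag when nothing is significant, so group
averages stay defined. ISPC values are baseline-corrected per pair and
frequency, masked, and purged of volume conduction: per pair x frequency and
analysis window, the per-trial mean phase difference is tested for clustering
toward 0 or toward $\pi$ with one-sided Gaussian v tests
($V = nR\cos(\bar\theta - \mu)$, $u = V\sqrt{2/n}$, $\alpha$ = 0.05 each),
and flagged entries contribute 0. A pair is connected when its
band (5-14 Hz) x window mean of the masked, corrected ISPC is strictly
positive; CD is evaluated during HF suppression (0.08-0.18 s) and
immediately after (0.18-0.3 s), with regional means over frontal (M2, M1),
parietal (S1, PA, RS) and occipital (V2, V1) electrode groups.

### PCI^ST

`pcist` computes the SVD of the trial-averaged response restricted to the
response window (0-0.6 s by default; 0.08-0.6 s for the post-onset value),
keeps the smallest leading set of spatial components reaching 99% of the
variance, projects each onto the full epoch, and drops components whose
response/baseline rms ratio falls below `snr_min` (default 1.8). Per
component, the distance matrix of absolute differences (embedding dimension
1) is built separately for the baseline (-0.5 to -0.005 s) and response
segments; for each of 100 thresholds spanning (0, max distance] linearly,
state transitions are counted as changes of the recurrence pattern along the
time axis, normalized per time sample; $\Delta$NST is the maximum over
thresholds of NST$_{resp}$ $-$ 1.2 $\cdot$ NST$_{base}$, clipped at 0 so the
index is nonnegative and the surrogate calibration below is attainable.
Because the threshold grid spans the observed distance distribution and the
SNR is a ratio, PCI^ST is exactly invariant to global amplitude rescaling
and to channel permutations. `calibrate_snr_min` draws 16 surrogate pairs of
non-overlapping 0.5 s non-response segments (t < 0 or t > 1.5 s), computes
each surrogate's components and transition contrasts once, sweeps the
candidate gates, and returns the smallest for which the median surrogate
PCI^ST is zero. `pcist_timecourse` repeats the computation in 0.1 s windows
shifted by 0.02 s up to 1.1 s (51 windows), re-deriving components per
window, consistent with the fixed-window definition.

## The synthetic-session generator

`simulate_session` produces sessions with the statistical structure the
analysis assumes, with every draw recorded in a ground-truth object, so
parameter-recovery tests can compare measured outputs against planted inputs.
Defaults mirror the study geometry: 90 trials, the 16-electrode bilateral
montage with bregma-referenced coordinates, 500 samples/s, epochs -5 to 5 s,
and a per-state template:

* **Background**: white noise shaped in the frequency domain to
  $1/f^{|\beta|}$ with state exponents $\beta$ = -1.4 (wake), -3.0
  (propofol/sevoflurane), -1.0 (ketamine), a plateau below a 4 Hz knee, and
  the squared magnitude of the 0.5-80 Hz band-pass applied — the generator
  emulates *preprocessed* signal. The knee reflects the physical fact that
  EEG spectra level off below the slow-oscillation band; without it, an
  unbounded low-frequency peak leaks through the finite-window periodogram
  and biases the 20-40 Hz slope estimate of steep spectra. Background rms is
  30 µV (wake-like) or 60 µV (slow-wave states).
* **Evoked response** (added from t = 0, amplitudes decaying exponentially
  with grid distance from the stimulation site in right M2, length constant
  6 mm): a locked early biphasic deflection (150 µV, 0.006-0.03 s); a
  per-channel oscillation bank whose phase is shared across trials (small
  0.3 rad jitter) for the locked duration — 0.32 s in wake, 0.13 s under
  propofol/sevoflurane, 0.23 s under ketamine, with a fast onset and a
  damped tail ending at the locked duration; a slow-component half-wave
  (40-60 µV peaking at 0.13-0.15 s); and an occipital coupling bank at 10 Hz
  shared by V1/V2 with quadrature phase offsets (0, π/2, π, 3π/2), so the
  planted coupling carries genuine non-zero lags — zero- or π-lag coupling
  is precisely what the volume-conduction test removes. The oscillation bank
  spans 8-25 Hz in wake but 8-10 Hz in the anesthesia-like states, whose
  responses are slow-dominated; this also keeps locked oscillatory energy
  out of the 20-40 Hz detection band, where 3-cycle wavelets have a spectral
  SD of f/3 and would otherwise smear theta-alpha amplitudes into the HF
  readout. Anesthesia oscillation and coupling amplitudes (20-30 µV) are set
  near the background amplitude in their own band for the same reason.
* **HF gain profiles** multiply the > 15 Hz part of the background:
  wakefulness carries a sustained +4.1 dB activation (0.04-0.55 s);
  anesthesia-like states an OFF period of -3 dB (power) over 0.08-0.18 s
  with sharp 5 ms edges; late non-locked HF bursts (+3 to +4 dB, 0.15 s)
  occur per channel with probability 0.33 (propofol/sevoflurane) or 0.9
  (ketamine). The -3 dB depth makes the planted suppression unambiguous at
  the pointwise bootstrap resolution (about 1 dB at 90 trials); the
  channel- and rat-averaged HF readout of such sessions comes out around
  -1 dB because masking and wavelet smoothing dilute the planted depth.

`paired_conditions` emulates the within-animal design: each pair shares
per-channel log-normal gains (SD 0.2) while trial noise is independent, and
all child seeds derive deterministically from one master seed.

What the generator does **not** emulate: biophysical volume conduction
(beyond duplicate-channel constructions used in tests), non-stationary
background (drowsiness, burst suppression), electrode artifacts other than
injected baseline outliers, stimulus-intensity dependence, and any
correlation structure between background and evoked components. Passing
recovery tests on these sessions therefore demonstrates that the analysis
measures what it claims on data satisfying its assumptions — not that real
recordings satisfy them.

## Numerical choices and degenerate inputs

* Identical trials give zero rejection SD; the strict `>` comparison then
  rejects nothing.
* Zero-magnitude wavelet coefficients carry no phase and enter phase
  clustering as zero phasors, diluting rather than corrupting the mean.
* An all-zero evoked response yields zero components and PCI^ST = 0, not an
  error; a constant component has zero transitions at every threshold.
* Components with a silent baseline have infinite SNR and are kept.
* SVD component signs are fixed (largest-magnitude loading positive) for
  reproducible reporting; PCI^ST itself is sign-invariant.
* The exact signed-rank test doubles mid-ranks so the tie-aware permutation
  distribution stays integral; zero differences are dropped and flagged.
* Fully tied Friedman blocks report statistic 0 and p = 1 rather than NaN.

## Problem sizes used by the test suite

The packaged tests run the full study geometry where the claim depends on
it: direction fidelity uses 9 default wake/propofol pairs of 90 trials x 16
channels each (so an all-same-sign result reproduces the exact two-tailed
signed-rank p of 2/512 = 0.0039), and parameter recovery uses single
90-trial sessions per state and per exponent. Type-I-error and oracle checks
use smaller constructions (2-8 channels, 20-90 trials) where the property
being tested does not depend on the montage size.

## Known limitations

* The NST fine structure (threshold-grid size, baseline weighting, per-sample
  normalization) follows the published sketch of the state-transition
  recurrence metric; absolute PCI^ST magnitudes are therefore
  implementation-defined and should only be compared within one
  implementation. Orderings and invariances are implementation-independent.
* The ITPC drop uses strict "last significant sample" semantics; with a
  pointwise-calibrated null this estimator would be unstable, which is why
  the masks use the baseline-extremes null described above.
* The v-test granularity (per pair x frequency on per-trial window-mean
  phase differences) is one of several defensible readings; it is logged so
  alternatives can be compared.
* EDF import covers continuous, single-rate recordings only; events arrive
  separately as delimited text.
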