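# percort

Perturbational complexity and phase-locking analysis of cortical evoked
responses in multichannel epidural EEG.

A single current pulse delivered to the cortex evokes a response whose
spatiotemporal structure tracks brain state: long-lasting, differentiated and
phase-locked in wakefulness; collapsed to a stereotyped slow wave with a
high-frequency "OFF period" under propofol or sevoflurane; intermediate under
ketamine. `percort` implements the full analysis chain behind these
measurements — preprocessing, Morlet time-frequency power with bootstrap
significance, spectral-exponent estimation, OFF-period and late-HF detection,
intertrial/intersite phase clustering, functional connectivity degree, the
state-transition perturbational complexity index, and the group-level
nonparametric statistics — plus a seeded synthetic-session generator with
full ground truth, so every stage is verifiable without access to animal
recordings.

## The statistics at the core

* **PCI^ST** = N_C x mean(ΔNST): the number of SVD components of the evoked
  response that account for 99% of the response-window variance and pass a
  signal-to-noise gate (SNR_min = 1.8, calibrated so 16 noise surrogates have
  median zero complexity), times the mean number of significant state
  transitions per component (a recurrence-quantification metric contrasting
  response against weighted baseline, maximized over a threshold grid).
* **ITPC**_tf = | n⁻¹ Σ_r exp(i k_tfr) |: intertrial phase clustering, the
  modulus of the trial-mean unit phasor of phase k at a time-frequency
  point; the *ITPC drop* (last significant 8-40 Hz band-mean value in
  0-0.8 s) measures the duration of the deterministic response.
* **ISPC**_tf = | n⁻¹ Σ_r exp(i (k_x - k_y)_tfr) |: the same clustering on
  phase differences between channels x and y; after baseline correction,
  bootstrap masking and exclusion of zero/π-lag (volume-conducted) pairs by
  Gaussian v tests, the **connectivity degree** of a channel is its fraction
  of significantly connected partners (normalized by channels − 1), averaged
  in 5-14 Hz within 0.08-0.18 s and 0.18-0.3 s.
* **Spectral exponent**: the 20-40 Hz log-log slope of the trial-averaged
  periodogram of spontaneous activity, indexing the redistribution of power
  toward low frequencies under anesthesia.

## Worked example

Simulate one wakefulness-like session at the default study geometry
(90 trials, 16-electrode bilateral montage, 500 samples/s, epochs −5-5 s
around the stimulus) and run the full pipeline:

```r
library(percort)

sim <- simulate_session(state_template("wake"), seed = 42)
features <- analyze_session(sim$epochs, seed = 7)
print(features)
#> <session_features> state wake
#>   PCI-ST (0.08-0.6 s): 80.03 | ITPC drop: 0.351 s | HF (0.08-0.18 s): 4.09 dB
#>   CD 0.08-0.18 s: 0.383 | CD 0.18-0.3 s: 0.358 | exponent: -1.45 | late-HF p: 1.00

print(features$pcist_late)
#> <pcist_result> PCI-ST = 80.03 (7 components, mean dNST 11.43)

cal <- calibrate_snr_min(sim$epochs, seed = 8)
cal$snr_min                    # smallest gate with median-zero surrogates
#> [1] 2.1
median(cal$surrogates)
#> [1] 0
```

Reading the output: the evoked response decomposes into 7 independent spatial
components averaging ~11 state transitions each (PCI^ST ≈ 80, high
complexity); the phase-locked response lasts 0.351 s (the planted locked
duration is 0.32 s); 20-40 Hz power in 0.08-0.18 s sits 4.1 dB *above*
baseline (no OFF period — wakefulness); about a third of channel pairs are
significantly phase-coupled after the volume-conduction screen, and the
spontaneous spectrum has the shallow (−1.45) slope of an activated cortex. A
propofol-like session (`state_template("propofol")`) yields the opposite
profile: PCI^ST under ~10, ITPC drop near 0.15 s, negative HF dB with an OFF
period detected on every channel, and connectivity degree near zero after
the suppression.

Group-level contrasts use `wilcoxon_exact`, `bca_mean_diff`,
`weighted_linfit`, `mann_whitney` and `friedman`; paired state comparisons
are generated by `paired_conditions`, which shares per-animal channel gains
within each pair.

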