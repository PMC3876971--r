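# oscitrack

Quantifying how the quasi-rhythmic amplitude envelope of continuous speech is
tracked by multiplexed cortical oscillations.

Speech carries information at nested time scales — prosodic (~1–3 Hz),
syllabic (~3–7 Hz) and phonemic (~35–45 Hz) — and cortical oscillations form
a matching hierarchy: delta and theta phase align to the slow envelope
modulations, gamma amplitude is modulated by theta phase, and acoustic
"edges" (a silence followed by a sharp envelope rise) reset low-frequency
phase. `oscitrack` implements the full information-theoretic analysis chain
used to characterise these mechanisms from source-level neural channel time
series and a speech envelope, together with a synthetic-data generator whose
ground-truth couplings make every stage of the chain testable.

## What it computes

* **Wideband speech envelope** — nine band-pass filters equidistant on the
  Greenwood cochlear map between 100 Hz and 10 kHz (4th-order Butterworth,
  forward and reverse), Hilbert magnitudes averaged across bands
  (`wideband_envelope()`).
* **Band-limited phase/amplitude** — zero-phase Butterworth band-limiting at
  centre ± 1 Hz (± 5 Hz above 40 Hz) and the analytic signal
  (`band_limit()`, `analytic()`, `default_band()`).
* **Mutual information** — the direct (plug-in) estimator on ten
  equipopulated bins,

  `I(X;Y) = Σ p̂(x,y) log₂ [ p̂(x,y) / ( p̂(x) p̂(y) ) ]`,

  with quadratic-extrapolation bias correction: fit
  `I(N) = I∞ + a/N + b/N²` through the estimates at N, N/2 and N/4 samples
  and report `I∞` (`mi_plugin()`, `mi_qe()`). Speech–brain MI in all four
  phase/amplitude modes, frequency scans, within-channel phase–amplitude
  comodulograms with surrogate masks, and the complementarity (information
  gain) test `ΔI = I(S; B_phase, B_amp) − I(S; B_phase)`
  (`speech_brain_mi()`, `coupling_spectrum()`, `comodulogram()`,
  `complementarity()`).
* **Edge-locked analyses** — threshold-based edge detection (mean amplitude
  < 0.05 in the 400 ms before onset, > 0.05 in the 1 s after, 20-ms mean
  jump > 0.05, on the max-normalised envelope), epoching from −500 to
  1000 ms, three phase-locking value variants
  `PLV = (1/n) |Σ exp(i·ph)|`, oscillatory-sampling cross-correlation (max
  |r| over ±150 ms lags in the 0–500 ms window), circular–linear phase
  coding of edge amplitude, and the pre/post edge contrast of theta–gamma
  coupling (`detect_edges()`, `epoch()`, `plv_*()`, `sampling_correlation()`,
  `phase_amplitude_coding()`, `edge_locked_pac()`).
* **Group statistics** — lateralisation index `LI = (R − L)/(R + L)`
  (positive = right-dominant), sign-flip randomisation t-tests (500
  randomisations), Benjamini–Hochberg FDR, bootstrap percentiles
  (`lateralisation_index()`, `randomisation_ttest()`, `fdr_correct()`,
  `bootstrap_percentile()`).
* **Synthetic cohorts** — quasi-rhythmic envelopes with prosodic/syllabic
  modulation and burst/silence edges, and neural-like channels with
  configurable entrainment, speech-phase→gamma-amplitude coupling,
  within-channel nesting, amplitude-coded edge phase resets, and 1/f
  background (`envelope_spec()`, `coupling_spec()`, `simulate_envelope()`,
  `simulate_channel()`, `simulate_cohort()`), plus pipeline drivers
  (`default_config()`, `run_analysis()`, `run_recovery_study()`).

## Worked example

```r
library(oscitrack)

# a 40 s quasi-rhythmic envelope with 12 burst onsets
spec <- envelope_spec(duration = 40, n_bursts = 12, seed = 3)
sim  <- simulate_envelope(spec)

# a neural channel that entrains its theta phase to the envelope
ch <- simulate_channel(sim$envelope, sim$truth,
                       coupling_spec(phase_entrainment = c(theta = 0.8),
                                     snr = 1, seed = 5))

theta <- canonical_band("theta")
a_env <- analytic(sim$envelope, theta)
a_ch  <- analytic(ch, theta)
speech_brain_mi(a_env, a_ch, "phase-phase")
#> <mi_estimate> 1.3486 bits (bias-corrected; plugin 1.4023), n=38646, bins 10x10

# the same channel against the time-reversed envelope: chance level
a_rev <- analytic(surrogate_reversed(sim$envelope), theta)
speech_brain_mi(a_rev, a_ch, "phase-phase")
#> <mi_estimate> 0.0268 bits (bias-corrected; plugin 0.0243), n=38646, bins 10x10

# edge detection recovers the 12 constructed onsets
nrow(detect_edges(sim$envelope))
#> [1] 12
```

The first estimate says the channel's theta phase shares ~1.35 bits with the
envelope's theta phase (out of log₂ 10 ≈ 3.32 attainable with 10 bins); the
reversed-envelope surrogate shows what the estimator returns when the
temporal correspondence is destroyed — about zero after bias correction.

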