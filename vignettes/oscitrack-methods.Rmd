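---
title: "Methods: information-theoretic analysis of speech-envelope tracking"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: information-theoretic analysis of speech-envelope tracking}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The problem

Continuous speech is quasi-rhythmic at several nested time scales: prosodic
fluctuations around 1–3 Hz, syllables around 3–7 Hz, and phonemic detail at
tens of hertz. Cortical oscillations form a matching hierarchy, which
suggests a multiplexed tracking scheme: slow oscillations align their phase
to the slow envelope modulations, while the amplitude of fast (gamma)
oscillations is modulated both by the speech envelope and by the brain's own
slow phase. `oscitrack` provides the measurement chain for this hypothesis —
envelope extraction, band-limited phase/amplitude, mutual-information (MI)
couplings, edge-locked phase-reset analyses and group statistics — plus a
synthetic-data generator with known couplings so that every estimator can be
validated against ground truth.

## Envelope extraction

The wideband envelope is the mean of Hilbert magnitudes over nine contiguous
band-pass channels spaced equidistantly on the Greenwood cochlear map
between 100 Hz and 10 kHz. The human map parameters used are
f(x) = A (10^(a·x) − k) with A = 165.4, a = 2.1, k = 0.88 (recorded in the
`map_params` attribute of `cochlear_band_edges()`). Filters are 4th-order
Butterworth applied forward and reverse (zero phase, 8th-order magnitude).
Stereo audio is averaged to mono before filtering, which matches a
binaurally identical presentation.

Numerical realisation: at typical rates the narrow low-frequency bands make
the transfer-function form of the Butterworth filter numerically unstable,
so the design is carried in zero-pole-gain form and applied as a cascade of
second-order sections. Signals are padded by odd reflection before
filtering; the pad length scales with both the band's lower edge and its
bandwidth (6 / min(lo, bandwidth) seconds, capped at the signal length),
because a 1–3 Hz band rings for seconds. Hilbert transforms are computed on
a 5-smooth padded FFT length: mixed-radix FFTs degrade to quadratic cost on
prime lengths.

## Band definitions

Frequency scans use centre ± 1 Hz up to 40 Hz and centre ± 5 Hz above
40 Hz; the boundary centre 40 Hz is assigned to the narrow rule. The named
bands delta (1–3 Hz), theta (3–7 Hz) and gamma (35–45 Hz) are realised with
those literal edges. A scan band whose lower edge reaches 0 Hz (the 1 Hz
step) is realised as a low-pass at the upper edge. One practical consequence
of the narrow-band rule is worth noting: an amplitude modulation is only
visible inside an analysis band that is wider than the modulation rate, so
phase–amplitude coupling with modulation rates above ~1 Hz is detectable
only for amplitude carriers above 40 Hz, where the ± 5 Hz rule applies. The
canonical theta → gamma coupling satisfies this.

## Mutual information

All continuous variables are quantised into ten equipopulated bins. Binning
is rank-based (ties share the lowest rank and fall in the lower bin), which
makes every MI estimate invariant under monotone transforms — hence raw
amplitudes are used without a log transform, and phases are binned like any
other variable (for near-uniform phases the quantile bins approximate
equal-width circular bins). The plug-in estimator on the joint histogram is
biased upward by roughly (bins−1)²/(2 N ln 2); the package corrects it by
quadratic extrapolation, fitting I(N) = I∞ + a/N + b/N² through the
full-sample estimate and the means over two contiguous halves and four
contiguous quarters. Contiguous blocks (rather than interleaved subsamples)
respect the autocorrelation of band-limited signals. Negative corrected
values are reported as-is so null distributions stay centred on zero; where
a non-negative quantity is required downstream (the lateralisation index),
negative estimates are clamped to zero information. When a series is too
short to split, the estimator falls back to the plug-in value with a
warning. A 1-s margin at each end of continuous data is discarded before
binning to drop filter transients.

The complementarity test asks whether gamma amplitude adds information
about the speech envelope beyond the brain's theta phase:
ΔI = I(S; Bθ, Bγ) − I(S; Bθ), with the joint response formed as the product
labelling of the two binned responses. The reported magnitude (and percent
gain relative to I(S; Bθ)) uses bias-corrected estimates; the significance
test uses uncorrected estimates throughout, permuting Bγ within each stratum
of fixed Bθ label. The two tracks are kept separate deliberately: bias
correction improves magnitude accuracy but costs statistical power.

## Surrogates

Chance levels for continuous speech–brain coupling come from the
time-reversed envelope, which preserves the spectrum and amplitude
distribution while destroying temporal correspondence. For epoched data the
null pairs each amplitude trial with the phase of a different random trial
(a derangement). For continuous within-channel comodulograms the null
circularly shifts the amplitude bin labels by random offsets of at least
1 s; the significance mask compares plug-in estimates on both sides so the
nominal false-positive rate is preserved.

## Edges and edge-locked analyses

An edge onset is the first sample of the max-normalised envelope at which
all three criteria hold: mean amplitude below 0.05 in the preceding 400 ms,
above 0.05 in the following 1 s, and a > 0.05 difference between the 20-ms
means after versus before. Later candidates within 400 ms of an accepted
onset are suppressed. Because the criteria are windowed means, the first
qualifying sample precedes an abrupt amplitude rise by up to one 20-ms
half-window; the generator therefore records the operational onset (the
first criteria-satisfying sample of the clean envelope) as ground truth
alongside the raw burst-gate time.

Trials are cut from −500 to 1000 ms around onsets. Three PLV variants are
computed across trials (phase, phase difference to speech, and left–right
phase difference) and averaged in baseline (−200–0 ms), early (100–300 ms)
and late (400–600 ms) windows; window means are compared with paired tests
across participants or replicates. The oscillatory-sampling analysis
cross-correlates cos(phase) or amplitude with the envelope over 0–500 ms at
lags up to ±150 ms, takes the maximum absolute correlation over lags and
averages over trials; shuffling the envelope trial order gives its control.
Phase coding of edge amplitude uses the circular–linear correlation
r² = (r²cx + r²sx − 2 rcx rsx rcs)/(1 − r²cs) between the phase at +100 ms
and the maximum envelope amplitude in the 200 ms after onset, with a
permutation p-value. The edge-locked coupling contrast computes per-trial
plug-in MI between theta phase and gamma amplitude in the 500 ms before and
after onset; with only ~500 samples per window, 4 equipopulated bins per
variable are used there instead of 10 (configurable), and the bin count is
reduced further with a message if a window cannot support it.

## Group statistics

The lateralisation index is LI = (right − left)/(right + left), positive =
right-dominant; cells with zero total are excluded as undefined. Group
inference uses dependent-samples t statistics with a sign-flip randomisation
null (default 500 randomisations) and the (b+1)/(n+1) p-value estimator, so
p is never exactly zero; multiple comparisons are controlled by
Benjamini–Hochberg FDR via `stats::p.adjust`. Bootstrap percentile
thresholds resample participants with replacement (default 500 iterations,
95th percentile of the group mean).

## The synthetic-data generator

No generative model is claimed for real recordings; the generator is a
stand-in that reproduces the *measurable* structure of the study conditions
and is labelled as synthetic in every manifest it writes.

* **Envelope**: a silence floor (0.01) interrupted by bursts. Within a
  burst the envelope is the product of syllabic (4.5 Hz) and prosodic
  (1.5 Hz) raised-cosine modulators, each with per-cycle duration jitter of
  ±20% so the rhythm is quasi-rhythmic rather than periodic, scaled by a
  per-burst amplitude (uniform on [0.4, 1] by default). Burst durations are
  1.3–2.0 s and inter-burst silences 0.7–1.2 s, giving roughly one edge per
  3.2 s — comparable to the edge density of natural narrated speech — while
  guaranteeing that each onset satisfies the three edge criteria. Both
  modulators restart at phase zero at burst onset so onsets are sharp.
* **Channels** are sums of coupled components plus 1/f noise (white noise
  spectrally shaped with exponent 1):
  entrainment injects a unit-amplitude oscillation following the envelope's
  band phase at a configurable lag — following the *phase* rather than a
  band-passed copy keeps the channel's phase defined during silences, where
  the envelope's own band amplitude vanishes and its phase is arbitrary;
  speech-theta-phase→gamma-amplitude coupling and within-channel nesting
  modulate a gamma carrier's amplitude as 1 + depth·cos(phase), a monotone
  function of the coupling phase; edge resets restart a 5 Hz oscillator at
  each onset at phase₀ + gain·edge-amplitude, so the reset phase codes the
  edge size. Component powers are fixed (entrainment at RMS = strength,
  reset oscillator at RMS 1, modulated carriers at RMS 0.5) and the noise
  RMS is set from the requested signal-to-noise power ratio.
* **Cohorts** share one stimulus envelope (as in a single-story listening
  study); channel seeds derive deterministically from the master seed, so
  regeneration is byte-identical.

What the generator does *not* emulate: biophysical neural dynamics,
sensor-level mixing and noise correlations, inter-participant variability in
coupling strength (participants differ only by noise realisation),
articulatory structure of real speech, and non-stationarity over minutes.
Passing tests therefore demonstrate estimator correctness and pipeline
recovery of injected effects, not claims about any particular real dataset.

## Problem sizes and defaults

Simulated validation runs use envelopes of 16–70 s at 250–1017 Hz (the
default rate, 1017 Hz, mirrors a typical MEG recording rate), cohorts of 22
participants, 10 bins, 500 randomisations, 100–200 surrogates or shuffles,
and depth grids {0, 0.3, 0.6, 0.9}. These sizes give stable estimates for
every quantity while keeping a full validation run in minutes on one core.
The pipeline configuration (`default_config()`) exposes all of them; a bare
configuration reproduces the canonical settings (bins = 10, edge thresholds
0.05/400 ms/1 s/20 ms, epoch window −500–1000 ms, PLV windows as above,
n_rand = n_boot = 500, FDR q = 0.05).

## Known limitations

* The quadratic-extrapolation fit is exact through three points; it removes
  the 1/N and 1/N² bias but not higher-order terms, so a small residual
  (≲ 0.003 bits at n = 1000 with 10×10 bins) remains.
* Equipopulated binning of heavily tied data relaxes the equal-count
  guarantee (ties go to the lower bin).
* Zero-phase filtering commutes with time reversal only up to edge
  transients; analyses discard a 1-s margin for this reason.
* The comodulogram's narrow-band rule blinds it to phase–amplitude coupling
  whose amplitude carrier lies below ~40 Hz with modulation faster than
  ~1 Hz (see *Band definitions*).
* MI between a phase and a near-constant amplitude is flagged as degenerate
  rather than silently returned.
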