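---
title: "Speech envelope tracking and brain–network representational similarity"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Speech envelope tracking and brain–network representational similarity}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(envtrack)
```

## The scientific question

When people listen to continuous speech, low-frequency EEG activity tracks
the slow amplitude modulations of the sound — the speech *envelope*, whose
dominant rhythm is the ~5 Hz syllable rate (theta band). Speech-recognition
recurrent networks transform the same acoustic input through a hierarchy of
layers. `envtrack` implements a pipeline for asking two questions about that
correspondence:

1. **Envelope tracking.** Do the hidden layers of the network follow the
   stimulus envelope with a lagged, evoked-response-like profile, the way
   frontocentral EEG does?
2. **Representational similarity.** Do the pairwise *dissimilarities*
   between a network layer's responses to a stimulus set mirror the
   dissimilarities between EEG responses to the same stimuli — and is that
   alignment a consequence of training rather than architecture?

The second question needs a null reference: an **ensemble of untrained
(randomly initialised) networks** with the same architecture. Any
brain–network similarity that survives in the untrained ensemble is
"inherited" from the stimulus itself; only the excess in the trained network
is attributable to learning.

## The analysis pipeline

### Stimulus preprocessing

The modulation envelope of each stimulus is computed as:

1. magnitude of the analytic signal (Hilbert transform via FFT);
2. 25 Hz low-pass with a least-squares linear-phase FIR filter, applied
   with zero phase;
3. downsampling to the network frame rate (50 Hz by default, the 20 ms
   feature stride of the emulated acoustic model);
4. first derivative (first difference scaled by the rate, units 1/s);
5. half-wave rectification;
6. normalisation to unit area (samples sum to exactly 1).

The rectified derivative emphasises acoustic onsets — the envelope edges
that evoked responses lock to — and the unit-area normalisation makes raw
cross-correlation magnitudes comparable across stimuli of slightly
different durations (here 5.5–6.5 s).

### Cross-correlation analysis

EEG epochs are averaged over the four repetitions of each stimulus, then
over the 12 frontocentral channels, band-passed 1–20 Hz (zero phase),
downsampled to the envelope rate, and cross-correlated with the modulation
envelope:

$$c(\tau) = \sum_t \mathrm{env}(t)\, r(t + \tau),$$

a *raw* (unnormalised, not mean-centred) correlation over signed lags,
positive lags meaning the response follows the stimulus. The expected shape
is N1-P2-like: a negative lobe near 140 ms and a positive lobe near 220 ms.
Network layers are treated the same way, except that each unit is
correlated separately and only units whose peak absolute correlation
exceeds the 20th percentile across units are averaged (the nodes that
actually carry the dynamics).

Statistical reference comes from a **null pairing**: each envelope is also
correlated against the response to a randomly chosen *different* stimulus.
Per-stimulus peak values (extremum in an a-priori window, ±50 ms around
140 and 220 ms) are compared matched-vs-null with a two-tailed t-test.

### RSA

Representational dissimilarity matrices (RDMs) are Euclidean-distance
matrices over the stimulus set. For EEG, the 12 pooled channels'
post-onset series (truncated to the common 5.5 s window) are concatenated
per stimulus, an RDM computed per repetition, then averaged — one RDM per
participant. For a network layer, the unit × frame activations are
vectorised per stimulus. RDMs are compared with Spearman rank correlation
over the strictly-lower triangle (average ranks for ties); rank
correlation makes the comparison invariant to any monotone transform of
either system's distances.

The **layer profile** computes, per participant and layer, rho against the
trained network and the ensemble mean of rho against each untrained
network, then a per-layer two-sample t-test across participants
(df = 2·n − 2; 28 with 15 participants). A paired variant is available;
the default mirrors the degrees of freedom convention of the emulated
analysis. The **noise ceiling** bounds achievable rho given
between-participant variability: the upper bound correlates each
participant's RDM with the all-participant mean, the lower bound with the
leave-one-out mean. **Band-resolved RSA** filters the EEG in 2 Hz bands
(0–20 Hz) with Gaussian-frequency-response FIR kernels before rebuilding
RDMs; **electrode-resolved RSA** computes one RDM per electrode, tests
trained-vs-untrained per electrode × layer, and reports the mean trained
rho with non-significant coefficients set to exactly zero (uncorrected
α = 0.05 by default; a Benjamini–Hochberg flag exists but is off to mirror
the uncorrected map).

## The synthetic world

No EEG recordings or trained checkpoints ship with the package. Instead a
seeded generator produces data with exactly the structure the analysis
assumes, so that every pipeline stage is testable end-to-end:

* **Stimuli** — noise carriers with a stimulus-specific formant-like
  spectral profile, amplitude-modulated by a quasi-periodic ~5 Hz syllable
  envelope with 20% interval jitter; 5.5–6.5 s; RMS-normalised. The
  spectral identity matters: it gives untrained networks (which see
  acoustics, not envelope dynamics) something realistic to represent, so
  their RDMs are not trivially envelope-shaped.
* **EEG** — each channel carries the modulation envelope convolved with a
  biphasic kernel (difference of two σ = 20 ms Gaussians at 140/220 ms,
  negative lobe slightly stronger, emulating N1-P2), plus independent 1/f
  ("pink") noise; 128 channels, epochs −700…+7800 ms at 250 Hz. The
  12-channel frontocentral subset has unit response gain, other channels
  0.3. Per-channel SNR defaults to 0 dB and is anchored to a
  *stimulus-independent* reference response (a periodic syllable train
  through the kernel): anchoring noise to each stimulus's own signal RMS
  would leak stimulus identity into noise-only channels and corrupt
  specificity analyses. Participants differ by a gain in [0.8, 1.2] and a
  response-latency shift (sd 8 ms); repetitions differ by a gain in
  [0.7, 1.3] ("attention"). These participant × stimulus interactions are
  what place the noise ceiling below 1.
* **Trained network** — layer *l* activations are
  `-w_u · g_l · env(t − 140 ms) + noise`, with per-unit weights
  `w_u ~ U(0.5, 1.5)`, mixing gains `g = (0.1, 0.2, 0.3, 0.8, 0.5)`
  peaking at the recurrent layer 4, and white unit noise at 1.5× the
  layer-4 signal sd. The negative sign reproduces the trough polarity of
  raw cross-correlograms at the recurrent layer. The default noise level
  is deliberately high enough that RDM similarity does not saturate before
  layer 4 — at low noise, Euclidean RDMs under independent noise preserve
  rank order almost perfectly and every layer's rho hits the same ceiling.
* **Untrained ensemble** — genuine architecture-matched forward passes:
  three clipped-ReLU layers, a unidirectional LSTM, a fifth clipped-ReLU
  layer, weights uniform in [−0.5, 0.5] drawn from per-instance seeds, run
  on log-mel spectrogram features of the stimulus (26 channels, 20 ms
  stride). Defaults use 64-unit layers (desk scale; the emulated model is
  far wider) and 100 instances in the full profile.

Every generator is a pure function of (configuration, master seed,
indices); channel noise is seeded per channel so analyses may generate
only the channels they consume without changing the data.

**What a green test does and does not establish.** The synthetic world has
the *statistical shape* of the real problem — lagged envelope-following
responses in coloured noise, layer-graded envelope codes, acoustically
driven untrained representations, participant variability — so green tests
establish that the pipeline recovers planted effects at calibrated error
rates. They do not establish anything about real EEG, real speech, or a
real trained recogniser: real responses are not exact convolutions, real
representational geometry is far richer than an envelope code, and real
noise is not stationary 1/f.

## Numerical choices

* **Least-squares FIR design** solves the weighted normal equations of the
  type-I linear-phase design, band weights 1/bandwidth so narrow stop
  bands are not sacrificed. The order rule 4·(rate/transition) is capped
  at 4000 taps — beyond that the dense solve is intractable in pure R —
  so at 16 kHz the 25 Hz low-pass has a ~16 Hz transition, harmless ahead
  of 50 Hz decimation. Designs are cached.
* **Zero phase** everywhere via symmetric kernels with compensated delay;
  latency claims would otherwise be biased by filter delay.
* **Resampling** zero-stuffs by the reduced ratio p/q, filters with a
  Hamming-windowed sinc (half-width 10·max(p,q) taps) at half the lower
  rate, and decimates; output length is ⌈n·p/q⌉.
* **Hilbert transform** uses the exact DFT length up to 8192 samples and
  power-of-two zero-padding above (arbitrary lengths can hit degenerate
  mixed-radix FFT sizes); the padding perturbs only the last few
  milliseconds before the 25 Hz low-pass.
* **Percentile node selection** keeps nodes *strictly* above the
  percentile (type-7 quantile); if ties empty the selection the stage
  falls back to all nodes with a classed warning.
* **Degenerate statistics** are signalled, not hidden: zero-variance
  differences give t = ±∞ with p = 0 (or t = 0, p = 1 when all
  differences are exactly zero), constant RDM triangles raise a classed
  error, and peak extrema on a window edge are flagged `at_edge`.

## Open design points, resolved

* Peak statistics admit two conventions for a 25-stimulus comparison: a
  paired test on per-stimulus differences (df 24) or a two-sample test
  treating matched and null values as groups (df 48). Both are implemented
  (`paired_peak_test(mode =)`); the pipeline default is paired, which
  matches the per-stimulus pairing structure of the design.
* Whether node selection uses signed or absolute correlation values is not
  specified; the maximum *absolute* value is used, consistent with
  selecting nodes by tracking strength regardless of polarity.
* The EEG is downsampled to the rate of the preprocessed envelope (one
  envelope per stimulus at the network frame rate), not the reverse.
* Per-electrode RDMs follow the same per-repetition → average rule as the
  pooled analysis.
* The noise ceiling uses the standard mean/leave-one-out construction.

## Acceptance scaling

The acceptance suite (`tests/testthat/test-acceptance.R`) pins the counts
its criteria state (25 stimuli / 15 participants / 4 repetitions and snr
0 dB for planted-lag recovery; 500 simulated experiments for type-I error;
15 participants and 10 untrained instances for the layer gradient; 128
electrodes with 10 planted, 50 seeds, α = 0.05 for the electrode map) and
scales only unpinned dimensions to fit the single-CPU runtime budget; each
test states its reductions inline. The type-I, gradient and electrode-map
fixtures hold the stimulus set fixed across runs and re-seed only the
noise, as a repeated experiment with the same materials would.

## Worked example

```{r example, eval = FALSE}
cfg <- run_config("envtrack_out", profile = "test")
res <- cmd_all(cfg)

# where does the grand-average matched EEG correlogram peak?
g <- res$tracking$sources$eeg$matched
g$lags_ms[which.min(g$values)] # ~140 ms trough
g$lags_ms[which.max(g$values)] # ~220 ms peak

res$rsa$profile        # per-layer trained vs untrained comparison
res$rsa$noise_ceiling  # ceiling bounds from participant RDMs
```

## Known limitations

* The trained-network generator plants a linear, single-lag envelope code;
  it cannot probe nonlinear or multi-timescale tracking.
* The surrogate untrained networks share the architecture but not the
  width of the emulated model (64 vs 2048 units by default).
* Electrode maps are numeric only; no scalp-topography interpolation or
  plotting is provided.
* Importing real EEG from standard acquisition formats is out of scope;
  epochs enter as plain channel × time matrices with window metadata.
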