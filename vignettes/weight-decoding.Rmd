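---
title: "Decoding object weight from surface EMG: models and methods"
author: "emglift"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Decoding object weight from surface EMG: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(emglift)
```

# The problem

In a reach-grasp-lift paradigm a participant reaches for an object, grasps
it between thumb and index finger, lifts and holds it, and puts it back;
the object's weight is one of 165, 330 or 660 g. `emglift` implements an
automated pipeline that decodes the weight class from five channels of
surface EMG sampled at 4 kHz, without hand-engineered features: the
preprocessed time-domain signal itself is the feature vector, and a
manifold-learning step discovers its low-dimensional structure.

The pipeline is

1. **Preprocessing** — full-wave rectification, per-channel peak
   normalization, and a zero-phase 4th-order Butterworth band-pass
   (5–450 Hz), in that order (the filter runs on the rectified, normalized
   signal).
2. **Segmentation and assembly** — the first 8 s of each trial, every 5th
   sample, channels concatenated: 5 × 8 × 800 = 32,000 features per trial.
3. **Dimensionality reduction** — Laplacian Eigenmaps on a union
   k-nearest-neighbour graph (k = 8 by default) with simple-minded (binary)
   or heat-kernel weights, solving the generalized eigenproblem
   $Lf = \lambda D f$ with $L = D - W$ and keeping the $m$ eigenvectors
   after the zero eigenvalue. Out-of-sample trials are mapped with a
   Nyström extension. PCA, LDA, LLE and ISOMAP are available as baselines,
   each with its own out-of-sample transform, and a Levina–Bickel
   maximum-likelihood estimator provides an intrinsic-dimension sanity
   check.
4. **Classification and evaluation** — k-NN (bespoke), linear and RBF SVM
   (C = 32, γ = 0.01) and random forest, scored by per-class and macro F1
   under a stratified 90/10 split with 10-fold cross-validated grid search
   on the training set only.
5. **Sliding-window analysis** — the same pipeline applied to 100 ms
   windows stepped by 40 ms, spanning 0.74 s before to 1.82 s after touch
   onset, tracing when weight information appears in the muscles.

# Numerical choices

**Zero-phase filtering.** The band-pass is applied as the squared magnitude
response of the Butterworth design in the frequency domain with reflection
padding (padding lengths are chosen so the FFT length is 5-smooth). This
equals a forward–backward (`filtfilt`) pass away from the signal edges to
about `1e-4` and is roughly an order of magnitude faster at cohort scale;
`method = "filtfilt"` remains available and the two are cross-checked in
the tests. Zero phase matters because the windowed analysis aligns windows
to behavioural events: a causal filter would shift envelopes by tens of
milliseconds.

**Spectral solve.** The generalized problem $Lf = \lambda Df$ is solved via
the symmetric normalized Laplacian $I - D^{-1/2} W D^{-1/2}$, whose
spectrum lies in $[0, 2]$; eigenvectors are normalized to $f^\top D f = 1$
and signed so that the largest-magnitude entry is positive. Both choices
are conventions (the eigenproblem fixes neither) adopted to make results
bit-reproducible. A disconnected neighbour graph is a hard error with a
diagnostic suggesting a larger neighbourhood — mirroring the windowed
analysis, where windows under 100 ms stop producing connected graphs.
k-NN ranking ties break towards the lower index; exact duplicate points
are allowed (distance 0, heat weight 1), and extending a point that
coincides with a training point returns that point's coordinates (the
consistent limit of the extension formula).

**Nyström extension.** A new point x is tied to its k nearest training
points with weights $w_i$ under the fitted scheme and mapped by
$y_j(x) = \sum_i w_i f_j(i) / (d(x)(1 - \lambda_j))$, $d(x) = \sum_i w_i$.
This row-identity form reproduces every training point exactly from its own
graph row because $Wf = (1-\lambda)Df$. Note that for genuinely new points
the formula scales each coordinate by $1/(1-\lambda_j) > 1$; extensions
therefore sit within a relative distance of order $\lambda_j$ *outside*
the convex hull of their neighbours' embeddings, which is why the
geometric sanity check in the tests allows a 1% (of embedding diameter)
tolerance on hull membership.

**Grid search.** The axes follow the study protocol (neighbourhood 4–20,
σ in 0.1…1000, m in 1, 5, 10, …). For each neighbourhood/bandwidth cell the
eigenproblem is solved once per fold at the largest m and truncated for
smaller m. Because the single symbol k serves both the graph and the k-NN
classifier in the protocol, the search couples the two: a cell's k also
sets the classifier's k (independent overrides remain available outside
the search). Cells that fail (disconnected graphs, singular extensions)
are recorded with their reason and excluded from the argmax; ties prefer
smaller m, then smaller neighbourhood, then smaller σ.

**Intrinsic dimension.** The Levina–Bickel estimator with the
asymptotically unbiased $k-2$ normalization, averaged over points and over
$k \in [k_{\max}-2, k_{\max}]$. On 2000-point Swiss-roll and sphere
fixtures it recovers dimension ≈ 2.

**Macro F1.** The textbook F1 formula is binary; for the 3-class problem
the package reports the unweighted (macro) mean over classes, the standard
choice under class imbalance (the largest per-subject imbalance ratio in
the published counts is 0.61). With 22 held-out trials and three
imbalanced classes, label-permuted macro F1 concentrates around 0.2–0.45;
the tests use [0.15, 0.55] as the permutation chance band.

# The synthetic cohort generator

The study's recordings cannot be bundled, so `simulateCohort()` emulates
a cohort with the statistical structure the analysis assumes. Defaults are
the study conditions: 12 subjects with the published per-subject class
counts (2,645 trials in total), 5 muscles, 4 kHz, 10 s trials, and a
blocked design in which the weight repeats with probability
`pRepeat = 0.6` (the repetition rate is not quantified in the source; 0.6
is this package's documented choice, well above the 1/3 of an unblocked
design).

Each trial is built as *envelope × carrier + noise*:

* **Carrier** — per-muscle independent band-limited (20–450 Hz) Gaussian
  noise, synthesized spectrally, with a soft amplitude ceiling
  (`2.2·tanh(z/2.2)`) standing for the bounded superposition of a fully
  recruited motor pool. The ceiling keeps the per-trial peak statistic
  tight, which matters because the pipeline normalizes each channel by its
  peak.
* **Envelope** — a weight-independent flat-topped reach burst before touch
  (the arm transport; it deliberately dominates the channel peak so that
  peak normalization is weight-independent), a contact grip floor rising at
  touch, load-dependent force development, a lift transient, and a release
  edge at LED-off.
* **Weight coding** — object weight sets the centre of a continuous
  "neuromuscular effort" latent λ (class centres 0 / 3.3 / 6.6, per-trial
  uniform spread ±1.6). λ drives grip-force development time, load-phase
  duration, and — principally — the waveform of an oscillatory
  load-stabilization drive, modelled as a Gaussian process over λ
  (random-Fourier basis, 128 components, RBF length scale 0.35,
  frequencies 6–30 Hz). Trials at nearby λ therefore have strongly
  correlated modulation waveforms and classes occupy adjacent regions of
  one connected manifold: this is what makes the union k-NN graph
  connected *and* locally label-pure, the two properties the spectral
  pipeline needs simultaneously. Two drives are used: the steady-hold
  drive is locked to the trial clock and carries whole-trial
  decodability; the early grip drive runs in touch-relative time so that
  event-aligned windows see aligned waveforms. The per-muscle `classGain`
  multipliers additionally scale raw amplitude monotonically with weight
  (they cancel under peak normalization, but make the raw post-touch
  rectified amplitude strictly ordered across weights).
* **Anticipation** — optional pre-touch preparatory activity that replays
  the *previous* trial's grip pattern (the drive at the previous trial's
  λ), scaled by `anticipationGain`. Pre-touch windows therefore carry
  information about the current weight only through blocked repetition,
  which is exactly the mechanism proposed for above-chance pre-touch
  decoding.
* **Noise** — additive white Gaussian noise of sd `noiseSd`
  (default 0.05, weak relative to unit-scale activations). End-to-end
  macro F1 is non-increasing in `noiseSd`.

Event times are jittered but ordered: LED-on early in the trial, touch at
≈ 0.17–0.23 of the trial per subject with a small (0.3% of duration)
within-subject jitter, LED-off ≈ 4.8 s after touch at the default
duration. The tight within-subject touch jitter is a deliberate
stylization: clock-locked oscillatory structure decoheres under large
event jitter, and the generator trades realistic trial-to-trial timing
variability for a controllable, decodable ground truth. All envelope time
constants scale with trial duration, so shortened test trials keep the
full movement morphology. A subject's stream is seeded independently of
the others, so generating one subject at a time (the memory-friendly way
to handle the ≈ 4 GB full cohort) reproduces exactly its slice of the
full cohort.

What the generator does *not* emulate: motor-unit physiology, surface-
material effects, fatigue drift, cross-talk between electrodes, or
realistic event-time variability. Passing tests on synthetic cohorts show
that the pipeline recovers the structure this model plants — not that
real recordings contain that structure.

# Problem sizes used in the tests

The test-suite defaults keep everything at the study's sampling rate where
the quantity under test depends on it (feature counts, window lengths),
and scale trial counts or durations down elsewhere. The end-to-end check
runs all 12 subjects at full scale (220–221 trials of 10 s at 4 kHz each)
for three cohort seeds with the fixed pipeline LE(simple, k = 8, m = 10) +
k-NN(8); the windowed check uses five full-count subjects. The embedding
dimension for synthetic cohorts is m = 10 (full trials) and m = 10 per
window: the planted manifold is low-dimensional, and higher Laplacian
coordinates contribute only graph noise to k-NN distances. The 120
dimensions used for real recordings in the windowed protocol remain the
`windowConfig()` default; the study-scale value reflects the richer
geometry of real EMG.

# Known limitations

* The generator's separability is by construction; its noise dial changes
  the signal-to-noise ratio but not the family of waveforms.
* LDA on raw 32,000-dimensional features is rank-deficient at cohort
  sample sizes; it is intended for use after another reduction or on
  smaller feature sets.
* The heat-kernel bandwidth grid is linear in powers of ten; for data
  whose pairwise distances live on a very different scale the grid should
  be rescaled.
* `windowedDecoding()` re-fits one embedding per window offset and
  subject, which is faithful to the protocol but quadratic-ish in cost;
  failed window fits (disconnected graphs) are reported per subject, not
  silently dropped.
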