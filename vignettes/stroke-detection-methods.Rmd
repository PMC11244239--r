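---
title: "Methods: EEG connectivity/complexity features and the SE-augmented VGG classifier"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: EEG connectivity/complexity features and the SE-augmented VGG classifier}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(strokeEEG)
```

## The problem

Acute ischemic stroke disrupts the brain's capacity for synchronized
neural activity. On scalp EEG this appears as (a) weakened inter-channel
phase synchronization and (b) altered signal complexity. `strokeEEG`
implements a detection pipeline that turns 1-second EEG epochs into
channel-by-channel feature images — phase-synchrony off the diagonal,
complexity on it — and classifies them with a compact convolutional
network using channel attention. Evaluation is subject-level
cross-validation with accuracy, sensitivity, specificity and ROC/AUC.

The pipeline targets 19-channel recordings in the international 10–20
montage sampled at 256 Hz, with binary subject labels
(1 = ischemic stroke, 0 = non-stroke control).

## Preprocessing

* **Band limiting (1–35 Hz).** A cascade of a 4-pole Butterworth highpass
  at 1 Hz and an order-128 Hamming-window FIR lowpass at 35 Hz, each
  applied forward–backward (zero phase). The test suite asserts the
  properties that matter: a 50 Hz mains tone is attenuated to below 1% of
  its input amplitude (well beyond 40 dB), a 10 Hz tone passes within a
  few percent, and re-filtering already-band-limited noise changes its
  RMS by less than 2%, so the delta (1–4), theta (4–8), alpha (8–13) and
  beta (13–30) bands pass intact. This hybrid was chosen over an all-IIR
  bandpass after measuring two requirements against each other: a
  low-order IIR bandpass cannot deliver 40 dB at 50 Hz with a 35 Hz
  edge, and a high-order IIR transition band keeps re-attenuating on
  repeated filtering, breaking idempotence. The sharp FIR upper edge
  satisfies both.
* **Bad-channel repair.** Channels flagged as bad are replaced by an
  inverse-distance-weighted average of their four nearest good
  neighbours on the idealised unit-sphere 10–20 coordinates. This is a
  deliberately simple, testable interpolation; a full spherical-spline
  interpolator would fit behind the same interface.
* **Segmentation.** Non-overlapping 1-s windows; the trailing remainder
  is discarded.
* **Artifact rejection.** Manual artifact screening is replaced by an
  amplitude threshold (default 100 µV in the API, 200 µV in the pipeline
  defaults for synthetic cohorts, whose amplitude scale is known): an
  epoch is dropped if any channel exceeds the threshold in absolute
  value. This is an automation decision — it reproduces the *effect* of
  artifact screening (removal of high-amplitude segments), not a human
  expert's judgement.

## Phase Lag Index and correlation weighting

For two channels with instantaneous phases `phi_x(t_k)`, `phi_y(t_k)`
(angle of the analytic signal, computed per epoch by frequency-domain
construction), the Phase Lag Index is

    PLI = | (1/K) * sum_k sign( wrap(phi_x(t_k) - phi_y(t_k)) ) |

with the difference wrapped to (−π, π]. PLI is 0 when there is no
consistently signed lag — including pure zero-lag synchrony, which is
what volume conduction produces — and 1 for perfect asymmetric phase
locking. Two numerical choices:

* The absolute value is part of the definition used here (the common
  convention, and the only reading under which the index lies in [0, 1]).
* Differences smaller than 1e-9 rad count as sign 0, so numerically
  identical channels give exactly 0 instead of noise-driven values.
* Phases are computed on each 1-s epoch after filtering, with no epoch
  tapering; an option to trim the first/last 5% of samples from the sign
  average exists but defaults to off.

**Correlation weights.** For each channel pair (i, j), the subject-level
PLI (mean over the subject's epochs) of every stroke subject is compared
with that of every control subject — P×M ordered cross-group
comparisons. With `n_l` the count of comparisons where the stroke value
is larger and `n_s` where it is smaller (ties count to neither),

    w_ij = | n_l − n_s | / (P × M)  in [0, 1].

The absolute value makes the weight a measure of *consistency of
separation* in either direction; without it the quantity can be negative,
contradicting its stated range. The cwPLI matrix is the elementwise
product `PLI ∘ w`; since weights lie in [0, 1] it is bounded above by the
PLI matrix, and pairs that do not separate the groups are shrunk towards
zero — which widens the standardized group gap.

**Leakage policy.** Inside cross-validation the weights are computed from
training-fold subjects only and applied to held-out epochs. Whether the
original protocol did this is unknowable from the outside; computing
weights on all subjects would leak group statistics into the test folds,
so the package enforces the conservative choice (an epoch-level
alternative exists only for the plain-PLI ablation, which uses no
weights).

## Sample Entropy

SaEn(m, r) is −ln of the ratio of (m+1)-length to m-length
template-match counts under the Chebyshev distance, self-matches
excluded, a match being distance < r. Defaults are the field standard
for EEG: m = 2, r = 0.2 × SD of the epoch, which also makes the
statistic amplitude-scale invariant. Two edge rules:

* A constant epoch returns 0 (every template matches at both lengths).
* If no (m+1)-length pair matches, the statistic is −ln 0; it is capped
  at ln(K − m) with a warning so feature maps stay finite. The cap is the
  largest finite value the estimator could produce at that series length.

The Chebyshev template index runs over the full m samples (the printed
range in some descriptions, which drops the last sample, is treated as a
typo); the match-count denominator excludes the self-match. SaEn is
computed per 1-s epoch and per channel.

## Fusion and rendering

The fused feature is a C×C matrix: cwPLI on the off-diagonal cells
(upper triangle mirrored, preserving the symmetric heat-map layout) and
the per-channel SaEn vector on the diagonal, which carries no PLI
information. SaEn is rescaled to [0, 1] **per channel** with robust
bounds — the 2% and 98% quantiles over the training subjects' epochs,
values outside clipped — estimated from training data only. Two reasons
for this over a single global min–max: per-channel bounds remove the
large between-channel entropy differences, which are a subject/channel
identity cue rather than a class cue; and quantile bounds stop two
extreme epochs out of a thousand from dictating the scale and
compressing the class signal into a few colormap steps. On synthetic
cohorts this rescaling is what lets the entropy diagonal *add* accuracy
over cwPLI alone instead of adding nuisance variance.

The matrix is quantised through a fixed 256-entry blue-to-yellow
(viridis) lookup table with global bounds [0, 1] (the cwPLI range) and
upscaled to the network input size by nearest neighbour. Rendering is
deterministic, label-blind, and invertible up to quantisation (~1/256
per cell; a handful of adjacent colormap entries collapse to the same
8-bit colour). Low connectivity renders blue, high connectivity yellow,
so stroke-like epochs produce visibly "bluer" maps.

## The classifier

A VGG-16-census convolutional network with squeeze-and-excitation (SE)
channel attention after every pooling stage: 13 convolutional layers
(all 3×3, stride 1, same padding) in five stages of (2, 2, 3, 3, 3)
convolutions, a 2×2 max pool closing each stage, one SE block after each
pool (before flattening, including the last), and a three-layer fully
connected head ending in a 2-way softmax.

An SE block computes the per-channel spatial mean (squeeze), passes it
through a two-layer gate — hidden width C/r with ReLU, output width C
with sigmoid — and rescales each channel map by its gate value in (0, 1),
so the block can only attenuate, never amplify: |output| ≤ |input|
elementwise. The reduction ratio defaults to r = 16 with the hidden
width clamped to ≥ 1 for narrow variants.

Scaling: `width_mult` scales the stage widths (64, 128, 256, 512, 512)
and `input_size` the image; the layer census never changes. The desk
scale used throughout the tests is 32×32 input (five poolings reduce it
to 1×1; a 19×19 feature matrix loses nothing at this resolution),
width 1/16 and a 64-wide FC head — about 60k parameters, trainable on
one CPU core in seconds per epoch.

The network is implemented in the package itself: im2col-based 3×3
convolution and pooling kernels in C++ (BLAS for all dense products),
analytic backpropagation through every layer (verified against finite
differences), and He-normal seeded initialisation. Two conditioning
choices matter in the absence of normalisation layers:

* inputs are centred (x − 0.5) on entry;
* SE gate biases initialise at +2, opening the gates to ≈ 0.88 so the
  five attention stages start near an identity map. Half-open gates
  would attenuate activations by 2⁻⁵ and stall early training.

## Training and evaluation

Two protocols are configured:

* **Reference protocol** (`train_config()` defaults): plain SGD, batch
  512, learning rate 1e-4, up to 100 epochs, early stopping. These are
  the settings a full-size dataset and full-width network would use.
* **Desk-scale protocol** (`pipeline_config()` defaults): Adam
  (lr 1e-3, weight decay 1e-4), batch 64, up to 12 epochs, patience 4,
  global gradient-norm clip 5. Plain SGD proved brittle at this scale:
  a 13-layer normalisation-free network needs a large step to escape its
  initial softmax plateau, and the same step destabilises training after
  the escape; measured on synthetic cohorts, SGD runs either stalled at
  chance level or diverged after partial progress, while Adam converges
  in under ten epochs. The optimizer is configurable, so the reference
  protocol remains available.

Early stopping monitors the loss on a 10% subject-level validation split
and restores the best weights. If a run still ends with training
accuracy below 0.8 — an optimization failure visible without any test
information — it is retried with a fresh initialisation seed (up to
three retries, best-fitting attempt kept). Cross-validation can train a
small ensemble per fold (`n_models`, default 2 in the pipeline): members
differ only in initialisation/shuffling seed and their softmax outputs
are averaged, which damps the fold-to-fold variance that single small
networks show on small cohorts. All seeds derive deterministically from
the fold and master seed, so results are bit-reproducible.

Cross-validation is **subject-level** and stratified: all epochs of a
subject share a fold, so the classifier is always tested on unseen
subjects. An epoch-level split would leak subject identity and inflate
accuracy; it is not offered. Per fold the pipeline reports the confusion
counts, Acc = (TP+TN)/total, Sen = TP/(TP+FN), Spe = TN/(TN+FP) (as
percentages; undefined ratios reported as NaN), and ROC/AUC with the
class-1 softmax probability as score. AUC is the midrank concordance
statistic, identical to the trapezoidal area under the empirical ROC
with tie handling.

## The synthetic cohort generator

Real stroke EEG is not distributable, so the package ships a generator
producing the two class-separating effects this pipeline exploits:

* per channel, a sum of four band oscillators (centres 2.5, 6, 10,
  20 Hz, amplitudes 1.0, 0.8, 1.2, 0.6) whose phases drift slowly; a
  fraction `coupling_strength` of the oscillator power is shared
  cohort-wide and received by each channel with a fixed lag drawn once
  per montage from (0.1, π − 0.1) — nonzero lags, so the synchrony is
  detectable by PLI;
* 1/f-shaped noise scaled by `complexity_scale` plus white noise
  (`noise_sd` = 0.2), which raises Sample Entropy;
* the sum is scaled to ~30 µV and band-limited to 1–35 Hz.

Class defaults: coupling 0.6 (control) vs 0.3 (stroke) — separable but
not trivial at the 1-s epoch level — and complexity scale 1.0 (control)
vs 0.6 (stroke), reflecting the reduced complexity of ischemic EEG.
Both effects are clearly detectable yet noisy per epoch (the acceptance
script reports the subject-level standardized connectivity gap it
measures). Raising the complexity asymmetry much further was rejected
during design because broadband noise suppresses phase synchrony: a
strongly noisier control group would flip the *connectivity* gap's
direction, contradicting the clinical effect the generator must emulate
(controls more synchronized).
An optional pair-private oscillator lets tests construct cohorts in
which exactly one channel pair is differentially coupled, for
weight-recovery checks.

What the generator does **not** emulate: ocular/muscle artifacts,
electrode drift or line noise, inter-subject anatomical variability,
lesion topography (effects are spatially uniform), and non-stationarity
beyond slow phase drift. Passing end-to-end tests on these cohorts
therefore demonstrates that the pipeline recovers the constructed
connectivity/complexity structure — not clinical-grade performance on
real EEG.

Subjects are pure functions of (master seed, class, subject index);
default cohort sizes mirror a realistic study (20 stroke / 19 control,
~5 min each), while tests use scaled-down cohorts.

## Problem sizes used by the test suite

Unit tests run on cohorts of 2–6 subjects with 4–30 s of signal. The
end-to-end recovery experiment uses 10 + 10 subjects × 60 s (1200
epochs), subject-level 5-fold cross-validation, three feature ablations
(PLI, cwPLI, cwPLI+SaEn) and three cohort seeds with the desk-scale
network; the acceptance script runs the same design at one seed. These
sizes were chosen so the whole suite completes on a single CPU core in
well under half an hour while keeping every stage's statistics
meaningful.

## Known limitations

* The interpolation is inverse-distance, not spherical-spline; adequate
  for the automated-repair contract, coarser than clinical practice.
* The EDF writer/reader covers continuous 16-bit EDF with one record per
  second — not EDF+ annotations or discontinuous files.
* Sample Entropy is O(K²) per channel-epoch (fast in C++ at K = 256, but
  quadratic growth for long windows).
* The full-scale (224×224, width-1) network is architecturally exact but
  not practically trainable in this package's CPU implementation; the
  desk scale is the supported operating point.
* Accuracy figures on synthetic cohorts characterise the pipeline, not
  clinical performance.
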