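# strokeEEG

Rapid ischemic-stroke screening from scalp EEG. Acute ischemia disrupts
synchronized neural activity: inter-channel phase coupling weakens and
signal complexity changes. This package turns those two effects into a
classifier: it computes correlation-weighted Phase Lag Index (cwPLI)
connectivity matrices and per-channel Sample Entropy (SaEn) from
1-second EEG epochs, fuses them into channel-by-channel feature images,
and classifies the images with a compact VGG-style convolutional network
carrying squeeze-and-excitation (SE) channel attention, evaluated by
subject-level 5-fold cross-validation.

It is aimed at researchers prototyping EEG-based stroke detection:
all stages are exposed as plain R functions, real recordings can be read
from EDF, and a built-in synthetic-EEG generator provides two-class
cohorts with controllable coupling and complexity so the whole pipeline
is testable without clinical data.

## The method

**Phase Lag Index.** For channels x, y with instantaneous phases
φx(t), φy(t) (angle of the analytic signal, per 1-s epoch):

    PLI = | (1/K) Σₖ sign( Δφ(tₖ) ) |,   Δφ wrapped to (−π, π]

PLI ∈ [0, 1]; it ignores zero-lag synchrony (volume conduction) and is 1
for perfectly asymmetric phase locking. Epoch-level matrices are
symmetric with a zero diagonal.

**Correlation weights.** For each channel pair (i, j), the subject-level
PLI of every stroke subject is compared against every control subject
(P×M comparisons); with n_l the "stroke larger" and n_s the "stroke
smaller" counts,

    w_ij = | n_l − n_s | / (P × M)  ∈ [0, 1],

a measure of how consistently the pair separates the groups. The cwPLI
matrix is the elementwise product PLI ∘ w; inside cross-validation the
weights are always learned from training-fold subjects only.

**Sample Entropy.** SaEn(m, r) = −ln(B⁽ᵐ⁺¹⁾/Bᵐ), the template-match
ratio under Chebyshev distance with self-matches excluded (defaults
m = 2, r = 0.2·SD). Higher values mean a more irregular signal.

**Fusion and classification.** The fused C×C map carries cwPLI off the
diagonal and rescaled SaEn on it, rendered through a fixed blue-to-yellow
colormap as an RGB image. The classifier is a VGG-16-census network —
13 3×3 convolutions, 5 max-pools, 3 FC layers — with one SE block after
each pool: squeeze z_c = spatial mean, excitation
s = σ(W₂ δ(W₁ z)), rescale x̃_c = s_c·u_c. Width and input size scale
down for CPU work without changing the census; forward/backward passes
are implemented in the package (C++ kernels + BLAS).

## Worked example

Generate a synthetic cohort (10 stroke-like + 10 control-like subjects,
60 s each), run the full pipeline for the plain-PLI and fused features,
and print the cross-validated reports (a few minutes on one CPU core):

```r
library(strokeEEG)

cfg <- pipeline_config(
  synth    = synth_config(duration_s = 60, n_subjects_per_class = 10),
  features = c("pli", "cwpli_saen"),
  k        = 5,
  seed     = 7)
reports <- run_pipeline(cfg)
print(reports$cwpli_saen)
print(reports$pli)
```

```
<metrics_report> cwpli_saen, 5-fold subject-level CV (seed 7)
  mean  Acc 91.92%  Sen 89.00%  Spe 94.83%  (SD 4.46/9.36/2.39)
  pooled Acc 91.92%  Sen 89.00%  Spe 94.83%  AUC 0.9723
<metrics_report> pli, 5-fold subject-level CV (seed 7)
  mean  Acc 85.42%  Sen 84.83%  Spe 86.00%  (SD 3.21/8.94/9.27)
  pooled Acc 85.42%  Sen 84.83%  Spe 86.00%  AUC 0.9299
```

Accuracy is the fraction of held-out 1-s epochs classified correctly
(subjects never appear in both training and test folds), sensitivity is
the true-positive rate on stroke epochs, specificity the true-negative
rate on control epochs, and AUC the area under the ROC over pooled
epoch scores. The correlation weighting and the entropy diagonal
together add about six accuracy points over the plain PLI feature on
this cohort.

Lower-level entry points: `bandpass_filter()`, `segment()`,
`pli_matrix()`, `correlation_weights()`, `apply_weights()`,
`sample_entropy()`, `fuse()`, `to_rgb()`, `build_model()`,
`train_model()`, `cross_validate()`; `plot_connectivity_heatmap()` and
`plot_connectivity_graph()` (threshold 0.10) visualize the matrices.
A thin command-line wrapper lives at `inst/cli/strokeeg.R`
(`synth`, `run`, `summary` subcommands).

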