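---
title: "Detecting seizures in scalp EEG with Kolmogorov-Arnold networks: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Detecting seizures in scalp EEG with Kolmogorov-Arnold networks: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
library(eegkan)
```

# The problem

Scalp EEG review for seizure detection is slow, and automated detectors
built on multilayer perceptron (MLP) backbones tend to fit their training
hospital's data and degrade on recordings from other sites. This package
implements a detector whose classifier is a *Kolmogorov-Arnold network*
(KAN): a network that replaces fixed node nonlinearities with learnable
univariate functions on the edges. The package covers the full chain —
synthetic data generation, EEG preprocessing, KAN training, and
evaluation — so every stage can be exercised and tested on one machine
with no access to clinical corpora.

# The classifier

## Kolmogorov-Arnold layers

A KAN layer maps $x \in \mathbb{R}^{n}$ to $\mathbb{R}^{m}$ by

$$ y_i = \sum_{j=1}^{n} \phi_{ij}(x_j), $$

where each $\phi_{ij}$ is a learnable scalar function attached to the
edge $j \to i$. Stacking layers composes these sums; the classical
superposition form with widths $n \to 2n{+}1 \to 1$ is available via
`kan_exact_form()`, while `kan_model("I-32-16-O", ...)` builds the
general rectangular variant used for classification (two output nodes,
softmax, seizure-class probability as detector score).

Each edge activation is parametrized as

$$ \phi(x) = w_b\, b(x) + s \sum_{c=1}^{G+k} c_c B_c(x), $$

with $B_c$ a shared B-spline basis (grid of $G$ intervals, degree $k$),
$b$ a fixed residual "base" function, $w_b$ and the $c_c$ trained, and
$s$ a fixed per-edge scale. Defaults: $G = 5$, $k = 3$, grid range
$(-1, 1)$, base function `silu`. These follow common practice for spline
KANs; inputs are standardized so $(-1,1)$ covers most of their mass.
All of them are adjustable through `spline_config()`.

Numerical choices worth knowing:

* **Basis evaluation.** Vectorized Cox-de Boor recursion on a uniformly
  extended knot vector ($k$ extra knots each side), so the $G+k$ basis
  functions form a partition of unity on the grid range.
* **Out-of-range inputs.** Standardized features occasionally exceed
  $(-1,1)$. Rather than clipping (which kills gradients) or letting the
  basis collapse to zero, each basis function is continued linearly from
  the nearest grid boundary (first-order Taylor expansion of the boundary
  polynomial piece). Values and first derivatives stay defined
  everywhere.
* **Gradients.** Backpropagation is analytic throughout, including the
  spline-basis derivative $B'_{c}$; the test suite checks it against
  central finite differences at relative $10^{-4}$.
* **Grid adaptation** is off by default (`grid_update`); deterministic
  parameter counts and reproducible runs matter more here than the small
  accuracy gain of quantile-adapted grids.
* **Per-edge scale and biases.** Whether spline KANs should carry a
  trainable per-edge scale is a matter of taste; we store `spline_scale`
  (so the parametrization is explicit and the checkpoint format stable)
  but keep it fixed at 1 during training. No biases are used: a constant
  offset is representable by the spline itself.

Parameter accounting (`arch_stats()`, `cmd_info()`) counts, per edge,
$G + k$ spline coefficients plus the base weight plus the scale. Hidden
neuron totals and their percentage against a baseline architecture are
rounded half-up to two decimals. We deliberately do *not* claim any
particular "model size" ratio beyond this documented counting: parameter
ratios depend on the spline hyperparameters, so the package reports
`n_parameters` and `param_reduction_pct` under its own counting rule.

## Training

`train_kan()` minimizes softmax cross-entropy with minibatch Adam
(learning rate $10^{-3}$, batch 64 by default; SGD available). After
every epoch the validation AUROC, AUPRC, precision, recall and F1 are
recorded. Weight selection follows an AUROC-plateau rule
(`select_weights()`): the running best-AUROC epoch is kept (earliest on
ties) and training stops once AUROC has failed to improve for `patience`
consecutive epochs (default 10) — i.e. the weights retained are those
from when the AUROC metric stopped increasing. Runs are deterministic
given the seeds and single-threaded BLAS.

# The EEG front end

The pipeline fixes a 19-channel 10-20 montage (`MONTAGE_1020`) at
250 Hz; other rates are polyphase-resampled in `conform_recording()`.
Processing steps:

1. **Segmentation** (`segment_recording()`): consecutive non-overlapping
   12-s windows, trailing remainder dropped. A window is labeled seizure
   if it overlaps any annotated ictal interval (any positive overlap by
   default; a minimum-overlap-fraction rule is available). The
   any-overlap default maximizes seizure recall at the labeling stage;
   400 h of recording yield exactly 120,000 windows.
2. **Eye-artifact removal** (`run_ica()`, `score_eye_components()`,
   `remove_components()`): FastICA (logcosh contrast, deflation) factors
   the centered data $T \approx M A$ into time courses and topographies.
   Because ICA is only identified up to order and sign, both are fixed by
   convention — components ordered by descending explained variance,
   topography sign made positive at its largest-magnitude weight — so
   seeded runs are exactly reproducible. Components whose time course has
   $|r| \ge 0.8$ (Pearson, against the raw FP1 or FP2 signal) are zeroed
   and the recording rebuilt; a top-$k$ rejection mode exists. The
   correlation is computed against the raw fronto-polar channels (not a
   band-passed version): blinks dominate these channels broadband, and
   raw correlation keeps the screen assumption-free. ICA runs per 12-s
   window by default (matching the segmentation-first ordering of the
   pipeline); a whole-recording mode is offered for long files.
3. **STFT featurization** (`stft_features()`): 250-sample (1 s) windows,
   50% overlap, one-sided spectrum with the DC bin dropped — hence
   23 frames × 125 bins per channel for a 12-s segment. The taper
   (periodic Hann) and magnitude map ($\log(1+|X|)$, which compresses the
   heavy-tailed spectral magnitudes) are configurable; the frame/bin
   counts that the shape contract tests rely on are taper-independent.
4. **Standardization** (`feature_stats()`, `standardize_features()`):
   per-feature affine transform to zero mean / unit variance computed on
   the training split only, stored with the checkpoint, and re-applied
   verbatim at inference. Standard deviations are floored at $10^{-6}$,
   so constant features map to 0.

# The synthetic-EEG generator

The generator (`sim_config()`, `gen_recording()`, `make_dataset()`)
emulates the statistical structure the detector faces:

* **Background**: per-channel $1/f$ (slope 1 by default) colored noise
  plus an amplitude-modulated 8-12 Hz alpha rhythm that is strongest
  posteriorly. Real scalp EEG is strongly nonstationary, so per-window
  noise and alpha amplitudes are drawn from ranges (8-25 µV and 5-25 µV);
  this is what makes the classification problem non-trivial, since a
  quiet seizure must be distinguished from a loud background window.
* **Seizures**: tapered spike-wave bursts — a fundamental drawn from
  2.5-4.5 Hz with $1/m$-weighted harmonics — with random per-channel
  spatial weights and per-event amplitude (15-60 µV). Episode timing is a
  renewal process whose default rate (22.5/h) and durations (20-60 s) put
  the expected ictal occupancy at 25%, the class balance the training
  harness targets; exact onsets/offsets are annotated.
* **Blinks**: stereotyped 200-400 ms biphasic transients at Poisson
  times (15/min), 100-200 µV at FP1/FP2 with a steeply frontal topography
  (posterior gain 0.03). The planted blink time course is retained so
  removal can be verified against ground truth.
* **Out-of-distribution variant** (`ood_shift()`): the seizure
  fundamental moves to 5.5-7.5 Hz, per-channel gains jitter by 0.8-1.25,
  and the background slope steepens by 0.3 — mimicking a different
  acquisition site and population while keeping labels valid. A zero
  shift reproduces the in-distribution generator bit-for-bit.

`make_dataset()` draws the requested number of windows with an exact
seizure-window count (`round(n * ictal_fraction)`), runs each through
the preprocessing path, and can write the concatenated windows as an
EDF+ file with TAL annotations plus a sidecar CSV and a YAML manifest.
Every output is a pure function of (config, seed).

What the generator does **not** model: dipole/forward-model head
geometry, inter-channel correlation structure of real background EEG,
patient-level heterogeneity, electrode artifacts other than blinks, and
seizure morphologies beyond rhythmic spike-wave. Passing tests on this
material therefore demonstrates that the pipeline's machinery is correct
and that the architecture comparisons hold under controlled drift — not
that any particular clinical performance level would be attained.

# The desk-scale study

Two experiments run routinely (test suite and `scripts/acceptance.R`):

* **Separability**: on a high-SNR dataset (seizure amplitudes 50-80 µV;
  480 training + 160 validation windows) the compact `I-32-16-O` model
  must reach validation AUROC ≥ 0.95 within 20 epochs.
* **Generalization direction** (`generalization_experiment()`): the wide
  baseline `I-764-256-O` and the compact `I-32-16-O` are trained on the
  same moderate-SNR set and evaluated — frozen weights, training-split
  standardization — on the shifted-distribution set. Across 5 replicate
  seeds the compact model's median OOD AUROC should be at least the
  large model's: over-parametrized backbones latch onto
  training-distribution detail that does not survive the shift.

Problem sizes here (480/120/240 windows, 10 epochs, and band/time-pooled
features — canonical EEG bands δ, θ, α, β, low/high γ × 4 time bins ×
19 channels = 456 inputs instead of the full 54,625-dimensional
spectrogram) are the package's desk-scale defaults, chosen so the full
study runs in minutes on one CPU core while preserving the spectral
structure the comparison turns on. The full-resolution path
(`pool = NULL`) is identical code and remains available for larger runs.

# Known limitations

* FastICA with deflation can fail to converge for individual components
  on short segments; the decomposition records per-component convergence
  and the reconstruction residual, and the artifact screen works on the
  components as returned.
* The EDF reader/writer covers the subset of EDF/EDF+ the pipeline emits
  (16-bit, 1-s records, one annotation channel); it is not a
  general-purpose EDF library.
* AUROC/AUPRC are undefined for single-class inputs and reported as
  `NA` rather than guessed.
* Window-level scores are the end product; no event-level
  post-processing (merging adjacent detections, refractory periods) is
  included.
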