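---
title: "Methods: multiple-instance SERS diagnostics in sersmil"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: multiple-instance SERS diagnostics in sersmil}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

This vignette is the package's own account of its models, its synthetic
world, and the design decisions taken where the underlying methodology left
the choice open. It states no empirical result that the test suite or
`scripts/acceptance.R` does not itself compute.

## 1. The diagnostic model

### Multiple-instance presence scoring

A plasma sample is represented as a *bag* of roughly one hundred SERS
spectra scanned across a 10 × 10 grid of acquisition spots. Only part of a
cancer patient's circulating exosomes are tumour-associated, so only part
of the bag's spectra carry any cancer signature; the rest are
indistinguishable from healthy-control spectra. The package adopts the
standard MIL simplification: *every spectrum inherits its bag's label*
(0 control, 1 cancer), a per-spectrum 1-D convolutional network with a
sigmoid output is trained on those noisy labels, and the bag's diagnostic
score is the arithmetic mean of its per-spectrum scores. The mean
aggregation is exact by construction (`score_bag` = mean of
`score_spectra`, tested to 1e-12) and is what turns a noisy per-spectrum
signal — whose spectrum-level accuracy is intrinsically capped by the
witness rate — into a well-separated sample-level score.

The assumptions this rests on:

* label noise is one-sided (control bags contain *no* cancer spectra);
* witness spectra are informative individually (no combinatorial
  interactions across spectra are modelled);
* spectra within a bag are exchangeable — the spot position carries no
  information (true of the generator; approximately true of a uniform
  SERS substrate).

### Two-stage decision

A sample is called positive iff its mean score **strictly exceeds** the
cutoff; "did not exceed" ⇒ non-cancer, so a score exactly at the cutoff is
negative. The cutoff is chosen on *training* bags only, as the threshold
whose ROC point minimizes the Euclidean distance to the ideal corner
(FPR 0, TPR 1); ties are broken toward higher specificity, then toward the
lower threshold (a screening test prefers fewer false positives).

For positive samples, the spectra whose per-spectrum presence score
reaches `spectrum_positive_threshold` (default 0.5) are routed to six
one-vs-rest scorers trained on cancer bags only; each contributes the mean
of its outputs over the routed spectra, giving a six-entry score vector. A
one-hidden-layer MLP (16 units, softmax over the six organ classes) maps
the vector to the final call, with argmax ties broken toward the
alphabetically first type. The MLP absorbs the correlation structure of
the ensemble — several one-vs-rest scorers can fire at once — rather than
trusting a raw argmax.

Two points were genuinely open and are pinned here as package decisions:

* **What counts as a "positive signal" for routing.** Spectra at or above
  the 0.5 sigmoid level, with a logged fallback to the top-scoring decile
  when a gate-passing bag has none (possible, since the gate tests the
  *mean*). The threshold is exposed in `decision_config()`.
* **The negative class of each TOO scorer.** Other cancer types only, not
  healthy controls: the TOO stage operates strictly downstream of the
  presence gate, so controls never reach it at prediction time and
  including them in training would only dilute the between-type contrast.
* **One seed for all six TOO scorers.** The scorers share initial weights
  and shuffle/dropout streams. This is what makes ensemble training exactly
  equivariant under a permutation of the type labels (relabelling two types
  swaps the two trained scorers bit for bit, a tested invariant);
  independently seeded scorers would satisfy it only approximately.

### Integrator input standardization

The six TOO scores are standardized (train-set mean/SD per entry, stored
in the integrator) before entering the MLP. One-vs-rest sigmoid outputs
can sit on a compressed scale around 0.5 — especially early in training or
at small sample sizes — while the class information lives in the *relative
pattern* of the six entries; without standardization the MLP's gradients
vanish on that scale. This is a deterministic, training-set-only transform
and therefore leaks nothing from the test split.

## 2. Network engine

No deep-learning framework is available to the package, so the scorers are
trained by an internal engine: im2col-style 1-D convolution expressed as
one BLAS matrix product per layer (C++ kernels for the column assembly,
max-pooling and their backward passes), ReLU, max-pool, dropout before a
fully-connected layer, and a sigmoid or softmax head; optimization is
mini-batch Adam (β₁ = 0.9, β₂ = 0.999, ε = 1e-8) on weighted cross-entropy.
Weight initialization is He-scaled Gaussian under a fixed seed; batch
shuffling, dropout masks and the validation split all derive from the
training seed, so training is bit-reproducible. The analytic gradients of
every layer are verified against central finite differences (tolerance
1e-7) in `test-nnet.R` — that test is what licenses trusting the rest of
the training stack.

Default architecture: three convolution blocks of (8, 16, 16) filters,
kernels (9, 5, 5) channels, max-pool 3 after each, dropout 0.3, a
32-unit fully-connected layer. This is a deliberately compact member of
the family indicated by the structural sweeps for this problem (first-layer
kernel below ~10 channels, later kernels ~5, dropout under 0.5,
fully-connected size uninfluential): the package targets a single CPU, and
this configuration trains the full seven-network desk-scale experiment in
minutes while leaving the acceptance margins intact. Class imbalance is
handled by inverse-frequency loss weights (default on); 20 % of training
spectra, stratified by label, are held out per training run to monitor
overfitting, and per-epoch train/validation accuracy is kept in the model's
`history`.

## 3. Signal conditioning

Each stage is standard Raman practice; the underlying methodology names the
steps (despiking, baseline correction, denoising, 860 cm⁻¹ anomaly
filtering) but not the algorithms, so the algorithms are package choices,
all parameterized in `preprocess_config()`:

* **Despiking** — windowed modified-z test (window 11 channels, threshold
  8) against a running median; flagged channels are replaced by that
  median. The robust scale has a floor of 5 % of the trace's dynamic range:
  without it, noise-free or locally smooth traces give near-zero MAD and
  the apex of *genuine* sharp peaks would be clipped. Cosmic-ray spikes are
  an order of magnitude above the trace, so the floor costs no recall; the
  filter is idempotent on its own output.
* **Baseline** — asymmetric penalized least squares (Whittaker smoother
  with asymmetry p = 0.01, smoothness λ = 1e6 for ~1.3 cm⁻¹ channel
  spacing, ≤ 20 reweighting iterations, early exit on a stable weight
  pattern). The pentadiagonal system is solved by a banded LDLᵀ
  factorization in C++ (O(n) per iteration). The estimate hugs the lower
  envelope, so broad humps and linear drifts are removed while peaks
  survive; the output is *not* clipped at zero — small negative noise
  residuals are harmless downstream and clipping would bias them.
* **Denoising** — Savitzky–Golay (window 9, order 3), with one-sided
  polynomial fits at the edges so that polynomials up to the configured
  order are reproduced exactly everywhere.
* **Anomaly filter** — a spectrum is retained iff the maximum intensity in
  the 860 ± 15 cm⁻¹ window *strictly exceeds* the threshold. The original
  threshold was set manually; for reproducibility the package sets it to a
  percentile (default 5th) of the *training-split* band intensities, and
  records it in every `QcReport`. A percentile threshold intentionally
  trades precision for recall: all true low-signal anomalies fall far
  below it, and a small tail of weak-but-valid spectra may be discarded
  with them, which is the conservative direction for QC.
* **Normalization** — unit-vector by default (whether the original
  pipeline normalized is unstated): raw intensity varies a few percent per
  spot, and the filter stage has already consumed the absolute scale, so
  the models see shape only.

The order — despike → baseline → denoise → filter → normalize — is fixed
and pinned by tests; filtering must precede normalization because the
anomaly statistic is an *absolute* intensity.

## 4. The synthetic world

The generator emulates the statistical structure the analysis assumes,
with parameters fixed once:

* wavenumber grid 600–1800 cm⁻¹, 900 channels (covers every band the
  assay reports; the real instrument grid is unpublished);
* Lorentzian line shapes (line shapes are never specified; any smooth
  unimodal profile would serve, and the choice is config-fixed);
* shared strong bands at 860/1283/1597 cm⁻¹ (amplitudes 1000/750/850
  counts, widths 18/22/16 cm⁻¹) on every class;
* cancer-common difference bands at 691, 826, 938, 961, 993, 1144, 1245,
  1527 cm⁻¹ (amplitude 0.6 × the class amplitude) plus two organ-specific
  bands per type drawn from the reported subtle-variation list (amplitude
  150 counts by default), carried only by *witness* spectra;
* witness rate 0.5 for cancer bags (per-spectrum Bernoulli; the mixed
  per-spectrum score maps within real cancer bags motivate a rate well
  below 1, but no quantitative value is published — the witness rate is
  this package's abstraction, not a measured quantity), 0 for controls;
* per-spectrum multiplicative scale with CV 6 % (the acquisition
  uniformity figure), additive Gaussian noise SD 15 counts, a smooth
  baseline (constant + slope + broad Gaussian hump, ±15 % per-spectrum
  jitter), 3 % single-channel spike rate, 2 % low-signal anomaly rate
  (trace suppressed to 1–5 %);
* stage labels (`early`/`advanced`, fraction 0.5) are bag metadata only —
  no spectral stage effect is modelled, because none is described.

What a green test does and does not establish: the generator reproduces
the *geometry* the models rely on (partial witness structure, shared vs
specific bands, realistic artifact rates), so green end-to-end tests
establish that the pipeline recovers structure that is truly present, with
honest split hygiene. They do not establish clinical performance: real
exosome spectra have correlated, non-Lorentzian, instrument- and
batch-dependent variation, confounders (age, sex, benign disease), and
class signatures far subtler than two clean marker bands. Published
patient-cohort metrics are therefore *not* reproduction targets of this
package.

## 5. Evaluation choices

* ROC curves enumerate all distinct score thresholds; AUC is trapezoidal
  and equals pair-counting concordance with ties counted ½ (tested
  exhaustively on small sets).
* Fixed-operating-point metrics are conservative: sensitivity at 99 %
  specificity is the maximum sensitivity among thresholds *achieving* the
  specificity target, with no ROC interpolation.
* Confidence intervals are stratified percentile bootstrap over bags
  (resampling within each class, so no resample is degenerate),
  deterministic under a seed; whether the original intervals were
  bootstrap or analytic is unstated, and the bootstrap requires no
  distributional assumption.
* The precision–recall summary reports the step-integrated area (the usual
  average-precision estimator, which equals prevalence for uninformative
  scores) and the maximum F1 over the curve.
* Degenerate inputs are explicit: single-class label vectors are errors;
  all-tied scores yield a degeneracy warning from `choose_cutoff`; a bag
  emptied by QC produces an `unscorable` decision status, never a silent
  class.

## 6. Reproducibility

Every stochastic stage (cohort generation, split assignment, weight
initialization, batch shuffling, dropout, bootstrap) draws from a seed
derived from one master seed in `experiment_config()`; rerunning a config
reproduces the report byte for byte, and the split audit aborts if any
sample id appears on both sides. Configs serialize to JSON (`jsonlite`);
cohorts serialize to plain CSV (manifest plus one wide per-sample file).

## 7. Known limitations

* The synthetic world is favourable by design at its default amplitudes;
  it measures pipeline correctness, not clinical difficulty.
* The MIL assumption is the plain bag-label-inheritance form; no attention
  pooling or per-instance label refinement is attempted.
* The engine is CPU-oriented and desk-scale; it is not a general-purpose
  deep-learning library (no GPU, no autograd beyond the implemented
  layers).
* Wavenumber calibration across instruments, multi-channel (non-delta)
  cosmic rays, and stage-dependent spectral effects are out of scope.
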