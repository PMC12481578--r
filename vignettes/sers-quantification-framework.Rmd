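---
title: "Quantifying biomarkers from SERS spectra: models, assumptions and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying biomarkers from SERS spectra: models, assumptions and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

serskit implements a three-stage framework for quantifying a target analyte
from surface-enhanced Raman spectroscopy (SERS) measurements of complex
biological media: (1) spectral preprocessing with a denoising autoencoder
trained to strip biological background, (2) neural quantification models
with SERS-specific layers, and (3) a context-explainability stage that
clusters per-instance LIME explanations into "contexts" — the distinct
rationales the model uses — and matches each context to reference spectra.
The worked setting is serotonin quantification (0-9 uM) in lyophilized
urine spiked with epinephrine and dopamine, measured with cucurbit[8]uril
spacers; the built-in study design (`study_manifest()`) mirrors that
layout: 318 urine and 364 water spectra over samples A-M plus an
analyte-free background sample U.

This vignette documents the models, the tunable parameters, the synthetic
data generator that stands in for the unreleased measurements, and the
design decisions taken where the method leaves details open. It states no
empirical numbers of its own: every quantitative claim about the package is
computed by the test suite (`tests/testthat/`) or by
`scripts/acceptance.R`.

## Preprocessing

**Baseline correction.** `als_baseline()` is asymmetric least squares:
the baseline $z$ minimizes
$\sum_i w_i (y_i - z_i)^2 + \lambda \sum_i (\Delta^2 z)_i^2$ with weights
re-estimated for a fixed number of iterations as $w_i = p$ where
$y_i > z_i$ and $1 - p$ otherwise. Defaults are $\lambda = 1000$,
$p = 0.1$, $n = 10$ iterations, applied identically to every spectrum.
Because the penalty uses second differences, constants and straight lines
are reproduced exactly, and adding a constant to a spectrum shifts its
baseline by the same constant. The solver is a banded sparse Cholesky
(`Matrix`); the test suite checks it against a dense base-R re-derivation
to 1e-8.

**Normalization.** `minmax_normalize()` rescales each spectrum to [0, 1]
using only that spectrum's minimum and maximum. This matches the
processing order (per-spectrum baseline correction, then normalization,
no cross-spectrum statistics) but has a consequence worth stating plainly:
*absolute* intensity scale is discarded. A purely multiplicative
measurement jitter disappears entirely; what survives normalization is the
ratio structure of the spectrum — analyte peaks against each other and
against any background. Concentration information therefore reaches the
models through relative peak heights and through the curvature of the
saturating response, not through raw intensity. The
parameter-recovery fixtures in the tests deliberately skip normalization
(raw intensities, linear response) so that the recovery target is exactly
identifiable, and use a dense design of 28 concentration combinations
spanning the 0-9 uM cube: a three-analyte response surface sampled at only
a dozen combinations leaves a neural regressor free to deviate on unseen
combinations even when it fits the seen ones almost exactly.

**Savitzky-Golay derivative** (`sg_derivative()`) is the benchmark
preprocessing: second derivative of a fifth-order polynomial in a 33-point
window, computed with `signal::sgolayfilt` with respect to the sample
index. Edge points come from the polynomial fit of the first/last full
window so the output keeps the input length — downstream models need a
fixed dimension.

**Crop.** The analysis window is 300-2000 cm$^{-1}$. The instrument grid
(`sers_grid()`) is 937 uniformly spaced points with spacing 1700/841
cm$^{-1}$, laid out so that exactly 842 points fall inside the window with
the first at exactly 300.0: the only grid consistent with both the
full-spectrum length (937, used by the denoiser) and the cropped length
(842, used by the quantifiers). The extra 95 points sit below 300
cm$^{-1}$, where spectrometers typically record.

## The synthetic data generator

No measured spectra are distributed with this framework, so
`make_dataset()` generates labelled SERS-like mixtures with the
statistical structure the pipeline assumes:

* **Band libraries** (`default_band_library()`): per compound, a table of
  Lorentzian/Gaussian bands. The shipped positions are plausible and
  configurable, not literature assignments; what matters for the method is
  that each analyte has at least one unique band, that analytes overlap
  (epinephrine and dopamine share a band at 1269 cm$^{-1}$; serotonin and
  dopamine have near-coincident bands at 759/769 cm$^{-1}$), and that
  unit-concentration reference spectra are pairwise distinguishable
  (cosine < 0.9, asserted by tests). The urine background template mixes a
  sharp urea-like band near 1003 cm$^{-1}$ with broad humps.
* **Response model** (`response_model()`): spectral amplitude follows the
  saturating form $a_{\max}\, c / (k_{1/2} + c)$ with $k_{1/2} = 4$ uM —
  monotone, bounded, approximately linear far below $k_{1/2}$. This is the
  assay behavior that motivates a logistic calibration output layer.
  A `linear` mode (the low-concentration tangent) supports
  saturation-free fixtures.
* **Nuisance processes**: lognormal multiplicative scale jitter
  ($\sigma = 0.1$) drawn *independently* for the analyte signal and the
  urine background — so the signal-to-background ratio varies per
  measurement and survives normalization; additive Gaussian noise with sd
  0.01 (1% of the unit maximum clean amplitude); a mild polynomial
  baseline drift for the baseline corrector to remove. These defaults were
  chosen once so that raw-spectrum quantification is visibly degraded
  while denoised quantification remains feasible, mirroring the qualitative
  raw-versus-denoised gap the framework is designed to demonstrate.
* **Confounding**: in the built-in design every serotonin-free sample
  (A, B, F, U) carries either another neurotransmitter or pure background,
  and one sample (C) is pure serotonin. A quantifier trained on this
  design can learn dopamine/epinephrine presence as a proxy for serotonin
  absence — the failure mode the explainability stage exists to expose,
  and the tests assert it does.

What the generator does **not** emulate: competitive adsorption between
analytes at the nanoparticle surface, electromagnetic hot-spot physics,
pH/temperature effects, instrument wavelength error, or cosmic-ray spikes.
Passing tests on this generator therefore demonstrate that the pipeline's
logic is sound under its stated statistical assumptions — not that the
trained weights transfer to real urine measurements.

## The denoising autoencoder

`train_dae()` trains a fully connected encoder (400-unit ReLU layer, then
compression to a 200-dimensional code) with a mirrored decoder whose final
sigmoid reconstructs the full 937-point spectrum in [0, 1]. Pairs come
from `build_noisy_pairs()`: each baselined water-medium spectrum is
overlaid (plain addition, `overlay_noise()`) with a randomly selected
baselined background measurement from sample U, after which both members
are min-max normalized; 80:20 train/test split. Loss is MSE, optimizer
Nadam, 128 epochs at batch size 32 by default.

Two open details were resolved as follows. The reconstruction target is
the *clean* spectrum (noisy input, clean target — the denoising
objective), and the reported `test_mse` is measured against clean targets.
The background gain in the overlay is 1.0 (addition as measured), exposed
as a parameter. The denoiser operates on the full 937-point vector;
denoised spectra are cropped to 842 points afterwards for quantification.

## Quantification models

All four architectures are built by `build_model()` on a compact
reverse-mode engine written for this package (`R/nn-core.R`, with the
convolution hot path in C++). The engine is verified by finite-difference
gradient checks over every layer kind in the test suite.

The **core CNN** is: initial 25-point-kernel convolution (8 filters,
ReLU), average pooling (4), a *paired Tanh-ReLU* convolution block (one
13-point convolution whose pre-activation passes through tanh and ReLU in
parallel, concatenated), a "half-peak" 13-point ReLU convolution (half the
nominal 25-point peak width), pooling, and a 32-unit dense head. The
precise depths and widths of the original core architecture are not
public; these choices are this package's own, kept deliberately small so
that desk-scale ensembles train in minutes, and are exposed in the layer
constructors.

* `cnn_linear`: core CNN, linear output.
* `cnn_3pl`: core CNN with the **three-parameter logistic output**
  $f(z) = \mathrm{upper} / (1 + e^{-\mathrm{steepness}(z - \mathrm{midpoint})})$,
  all three parameters learnable, `upper` initialized above the maximum
  training concentration (10 uM for a 0-9 uM task). A regression head
  acts as a calibration curve, and assays saturate near the limits of
  quantification: the logistic output encodes exactly that prior. The
  output is bounded by `upper` at every training step by construction.
* `scnn`: the initial convolution is replaced by the **multiscale layer**
  (parallel kernels of 8, 25 and 50 points, 8 filters each, concatenated
  to 24 channels — a third of a peak, half a peak, a full peak), followed
  by the **local region-scaling layer**, which multiplies preregistered
  index regions by learnable scalars. Regions are meant to cover spectral
  ranges irrelevant to the target; `propose_scaling_regions()` derives
  them as ranges where every reference spectrum sits below a quantile
  threshold. Both layers are exactly linear in their input, so an impulse
  response equals the kernel itself (tested against a direct correlation
  oracle; cross-correlation convention, no kernel flip).
* `vit`: patch embedding of width 25 (matching the CNN's initial kernel;
  inputs are right-padded with zeros to the next patch multiple so no data
  is discarded), hidden size 64, six pre-norm transformer blocks with
  6-head self-attention, GELU MLPs and dropout 0.1, mean token pooling and
  a linear head. Since 64 is not divisible by 6, attention projects to
  heads x ceil(64/6) dimensions internally and back to 64 on output — the
  standard independent-key-dimension formulation.

**Training protocol** (`train_protocol()`): Adam, learning rate 0.001,
batch size 64, up to 256 epochs, MAE loss, early stopping with patience 64
and checkpointing of best-validation weights. `train_ensemble()` trains
`ensemble_size` members (100 in the full protocol) from derived seeds,
drops members with training MAE above 1 uM, and selects the surviving
member with minimal validation MAE; ensemble-average predictions over
survivors are also available, since which of the two feeds a headline
number is a reporting choice. An ensemble whose members are all dropped
reports `converged = FALSE` rather than failing.

**Split rules** (`split_dataset()`): held-out test samples (D, E) appear
exclusively in the test set; the held-out validation sample (F)
contributes all its spectra to validation; repeat spectra are shuffled and
split 90:10 with the validation count `ceiling(0.1 * n)` — the only
rounding that reproduces the published 218/46/54 partition of 318 urine
spectra.

**Metrics** (`evaluate()`): MAE (uM), MSE, and MPE. MPE divides by the
true concentration and is undefined at zero; it is computed over entries
with truth >= 0.5 uM (the floor is a visible, configurable parameter
rather than a hidden convention), and reported as `NA` when no entry
qualifies.

## Context explainability

The stage answers: *which rationales does the trained model actually use?*

1. **LIME** (`lime_explain()`): the spectrum is cut into contiguous
   25-point segments (about half a peak). Perturbed neighbors switch
   random segment subsets "off" by replacing them with the spectrum's
   global baseline level (its minimum). A ridge surrogate, weighted by an
   exponential kernel in the fraction of switched-off segments, yields one
   weight per segment plus an intercept. Per-segment perturbation limits
   record the range of values each segment took across the sample. The
   perturbation scheme is the standard tabular-LIME analogue; on a model
   that is exactly linear in segment means, the surrogate recovers the
   true coefficients (tested analytically).
2. **Flattening** (`flatten_explanations()`): one row per instance —
   weights, lower limits, upper limits — each column min-max normalized
   across the dataset.
3. **Latent space** (`fit_latent()`): a small VAE (32-unit encoder/decoder,
   beta-weighted KL with beta = 0.01, Adam) embeds the rows in two
   dimensions; the encoder means are the coordinates. Two dimensions are
   fixed by the method: contexts are selected by inspecting this plane.
4. **Contexts** (`cluster_contexts()`): K-means. The context count is a
   judgment call in the original workflow (visual inspection); the
   programmatic default scans k = 2..10 for the silhouette maximum, and an
   explicit k overrides it. On the built-in confounded design the
   silhouette criterion favors a coarse 2-cluster split (serotonin-bearing
   versus background-only); the study protocol's inspected choice of six
   contexts separates the confounder contexts as well, and the acceptance
   tests use k = 6 for that reason.
5. **Context summaries** (`context_regions()`): mean explanation (exact
   member average), mean spectrum, and top peak regions: each segment
   becomes a 3-D point (mean intensity, normalized absolute LIME weight,
   position z-score), points are K-means-clustered into 15 groups, groups
   are ranked by mean |weight| x mean intensity, and the top five are
   reported as index regions. Ranking uses absolute weights (a strongly
   negative region is as diagnostic as a positive one); signed weights are
   retained in the report.
6. **Matching** (`match_context()`): the context's mean spectrum and each
   clean reference spectrum are multiplied positionwise by the context's
   normalized absolute weight profile (each position inherits its
   segment's weight) and compared by cosine similarity,
   $S_{\cos} = A \cdot B / (\lVert A\rVert\, \lVert B\rVert)$. A reference
   identical to the context spectrum scores 1 regardless of weights;
   uniform weights reduce to plain cosine.

On the built-in design the tests require the qualitative outcome the
method exists to produce: at least one context whose top match is
serotonin (the model using the target's own peaks) and at least one whose
top match is dopamine or epinephrine (the model exploiting the
absence-of-serotonin confounder).

## Benchmarks and robustness

`run_benchmarks()` runs PLSR (via mixOmics, with the component count
capped at the effective data rank so noiseless low-rank fixtures remain
solvable), random forests, RBF-SVM and gradient boosting, each grid-searched
with 3-fold cross-validation on modest documented grids. A family that
fails on degenerate input becomes a failure row, not a crash; a constant
training target short-circuits every family to the intercept-only model.

`perturbation_test()` adds Gaussian noise with sd = level x per-spectrum
maximum intensity — the "X% noise" reference scale — either everywhere
(`universal`) or inside chosen regions (`localized`, typically the
explainability stage's top regions). Level 0 reproduces the unperturbed
MAE exactly; robustness is judged against a 0.5 uM MAE cutoff.

One subtlety the tests made visible: "more noise, more error *in
expectation*" presumes the unperturbed model is calibrated on the spectra
being perturbed. On held-out samples with unseen concentration
combinations the model carries a bias, and small noise can partially
cancel that bias, producing a dip in the MAE-versus-level curve. The
monotonicity property is therefore asserted on in-distribution
(validation) spectra; level-0 exactness holds everywhere.

## Reproducibility and problem sizes

Every stochastic operation takes an explicit seed; `derive_seed()` mixes a
master seed with stage labels so one integer reproduces a whole run
(`run_pipeline()` records per-stage seeds in its log). Training is
deterministic given the seed: identical losses across processes.

The shipped tests and the acceptance script run the framework at desk
scale, a deliberate choice so the whole suite executes on one CPU in
minutes: denoiser trained for 48 epochs; quantifier ensembles of 5 members
at 64 epochs (ordering comparisons) or 3 members at 200 epochs (parameter
recovery); LIME with 300 perturbations per instance over the full 318
urine spectra. The full-scale protocol (100-member ensembles, 256 epochs,
128 denoiser epochs) is the package default in `train_protocol()` and
`dae_config()`.

## Known limitations

* The generator's band positions are constructed, so absolute cosine
  values against its references are fixture properties, not chemistry.
* Per-spectrum min-max normalization removes absolute scale; tasks whose
  signal is purely multiplicative are unidentifiable after it.
* LIME explanations are a local surrogate, not the model; contexts
  inherit that approximation.
* The denoiser is trained on simulated water/background pairs; nothing
  here validates transfer to real patient urine.
* The ViT is included for architectural completeness and trains far more
  slowly than the CNNs at this scale; it is exercised lightly in tests.
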