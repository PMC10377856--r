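---
title: "Methods: spectral reconstruction and band-selected screening of fundus images"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: spectral reconstruction and band-selected screening of fundus images}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

This vignette documents the models, parameter choices and numerical
conventions behind `fundusHSI`, and what the synthetic validation does and
does not establish.

## The problem

Hydroxychloroquine (HCQ) accumulates in the melanin-rich retinal pigment
epithelium and, over years of exposure, damages photoreceptors around the
fovea. On an RGB fundus photograph the early signature is subtle: a small
change in spectral reflectance, concentrated — in the motivating clinical
work — in the 500–600 nm range. The package implements the full screening
chain: RGB image → per-pixel reflectance spectrum (401 bands, 380–780 nm)
→ group spectral comparison and band-window selection → band-selected
color reproduction → classifier comparison between original (ORI) and
band-selected (HSI) images.

No clinical images are available, so every stage is validated against a
synthetic world with known ground truth. The generator is therefore a
first-class part of the package, and its defaults define the study
conditions under which everything is tested.

## The camera forward model

Rendering integrates reflectance against an illuminant and observer
weights:

* **Observer weights**: the published piecewise-Gaussian analytic fit to
  the 2° standard observer (sums of asymmetric Gaussian lobes). We chose
  the analytic form over a tabulated fixture because it reproduces the
  observer to well under a percent of peak on any grid and keeps the
  package self-contained.
* **Illuminant**: a Planckian radiator at 6504 K normalized at 560 nm — a
  standard stand-in for average daylight. Nothing downstream depends on
  fine illuminant structure, because the calibration references are
  computed under the same camera model (the loop is closed by design).
* **White balance**: a von Kries diagonal scaling in XYZ mapping the
  scene (or window-restricted) white onto the sRGB white. Balancing in
  XYZ rather than linear RGB matters: a 500–600 nm band-limited white has
  no nonnegative RGB representation, so RGB-space balancing breaks down
  exactly where band-selected reproduction needs it.
* **Quantization**: sRGB transfer, then round-half-away-from-zero to
  8 bits. The rounding rule is stated so round-trip tests are bit-stable.

## The synthetic scene generator

Each scene is a reflectance cube built from four smooth spectral
signatures (background fundus, vessel, fovea, optic disc) blended by
spatial weight maps (parabolic vessel arcades leaving the disc, a Gaussian
foveal dip, a bright disc). The signatures are linear combinations of six
components: constant, linear tilt, melanin-like exponential decline
(length constant 270 nm), hemoglobin-like Gaussian dips at 540 and 575 nm
(width 15 nm), and a blue-absorbing macular-pigment-like band at 460 nm.
They mimic the qualitative shape of fundus reflectance — low in the blue,
rising toward the red, with hemoglobin structure — without claiming
biophysical accuracy.

On top of the anatomy:

* **Case effect** (`delta`, default 0.05): reflectance inside the case
  window (default 500–600 nm) is multiplied by `1 + delta` for label
  `hcq`. `spatial_extent = "fovea"` instead weights the effect by the
  foveal mask, used for localization experiments.
* **Age effect** (`age_slope`, default 5e-4 per year): an additive tilt,
  positive below 530 nm and negative above, proportional to `age − 60`.
  This reproduces the qualitative clinical observation that older eyes
  reflect relatively more at short wavelengths and less at long ones.
* **Diabetic retinopathy**: no spectral effect, by design — the clinical
  analysis found none.
* **Pixel noise** (`noise_sd`, default 0.005 reflectance units): i.i.d.
  Gaussian per pixel and band.
* **Scene-level confounder** (`nuisance_sd`, default 0): a random-amplitude
  smooth spectral perturbation with bumps at 470 and 635 nm (width 18 nm),
  essentially zero inside 500–600 nm. It is off in the default conditions
  and switched on (sd 0.25) only in the classifier-comparison corpus,
  where it realizes the condition that noise dominates outside the case
  window (see below).

Determinism is a contract: identical `(params, seed)` reproduce a cube bit
for bit, and every generator restores the caller's RNG state.

## Spectral reconstruction (RGB → 401 bands)

The conversion is a two-stage calibration regression:

1. **Color correction.** Device colors are linearized (sRGB transfer) and
   mapped to XYZ; all 20 monomials of (X, Y, Z) up to total degree 3 form
   the feature vector; unregularized least squares maps features onto
   reference tristimulus computed from the checker patch spectra under the
   camera model. Degree 3 is the smallest expansion that corrects typical
   camera nonlinearity; the term order is fixed and documented.
2. **Spectral regression.** Checker spectra are decomposed into a mean
   plus `k = 12` principal components (SVD); a ridge regression
   (`lambda = 1e-3`) maps polynomial features of the *corrected*
   tristimulus onto component scores. The ridge solve uses the SVD of the
   feature matrix, which stays stable as `lambda → 0` (the
   normal-equations form squares the condition number and loses half the
   available precision).

Reconstruction is `clip(μ + B s, 0, 1)` per pixel, with a unique-color
cache (exact, since the map depends on color alone). Two pixels with the
same RGB always get the same spectrum — the inverse cannot resolve
metamers, and we state that rather than hide it.

**The calibration target samples the scene manifold.** The 24 canonical
patches are region signatures at three brightness levels, their pairwise
midpoints, two age tilts and four window perturbations; the 100 random
patches are random region mixtures with random tilts, window gains and
confounder gains. A color checker is only informative for spectra like the
ones it will be asked to reconstruct; with this in-domain target the
training RMSE is ≈ 0.016 and the noiseless render→convert round trip is
≈ 0.015 reflectance units (the acceptance bound is 0.05). Checker patches
are kept smooth — tilts and window gains get logistic shoulders (6–8 nm)
so the maximum absolute second difference stays below 2e-3 per nm², which
the tests assert.

## ROI scheme and quality control

Five square patches: `F` at the fovea; `S1`/`I1` displaced vertically by
± the arcade half height at the fovea column shifted a quarter of the
fovea→disc distance toward the disc; `S2`/`I2` the same displacement
shifted a quarter away. The quarter-shift rule is a declared convention —
the clinical protocol placed patches manually and published no pixel
offsets. Coordinates are 0-based, row-major, origin top-left; crops are
half-open windows of exactly `size × size` starting at
`center − floor(size/2)`, clamped so they fit, with no padding. The
240-pixel patch of the clinical protocol is scaled as 240/512 of the image
side for smaller synthetic scenes.

Quality control computes the variance of the 4-neighbour Laplacian of the
green channel (sharpness), the fraction of pixels with any channel
saturated, and the fraction of all-black pixels. Thresholds:
`tau_s = 1e-4` (calibrated on clean synthetic renders across 48–512 px
scenes: a factor ≈ 4 below the least sharp clean render and ≈ 4 above a
σ = 8 blurred copy), `tau_hi = 0.1`, `tau_lo = 0.5`. The clinical source
states the exclusion rule but no numbers, so these are package choices,
and blur degrades the sharpness statistic monotonically by test.

## Band selection and color reproduction

Window selection scans every contiguous window of the requested width
(default 100 nm) and maximizes the mean absolute difference of group mean
spectra, ties toward the shortest wavelength; the implementation is
checked against exhaustive search. Reproduction multiplies spectra by a
hard window indicator (boxcar — the method is band *selection*, not
smooth weighting), integrates with the window-normalized illuminant ×
observer weights, white-balances against the window-restricted white
point (so HSI images are not uniformly dark or green), gamma-encodes,
optionally resizes bilinearly, and quantizes. With the full-grid window
this reduces exactly to the direct render, which the tests assert within
2 quantization levels.

## Cohort statistics

All tests operate on summaries so the published table can be reproduced
exactly from its printed numbers: pooled-variance two-tailed *t*
(pooled, not Welch — this is what reproduces the printed age p-value of
0.75); 2×2 Pearson chi-square *with* Yates continuity correction (the
printed 0.10/0.03/0.74/0.74 match only the corrected form); R×C Pearson
chi-square without correction (0.43); one-way ANOVA from `(mean, sd, n)`
triplets; size-weighted pooled means. Effect sizes are conventional
(Cohen's d, odds ratio with Wald CI, Cramér's V, eta-squared). The
published table's own effect-size and CI columns are internally
inconsistent with its footnotes (e.g. a sex "odds ratio" of 0.02 from
22/3 vs 45/21, and an age CI not reproducible from the printed summaries
by either pooled or Welch formulas); we report the conventional
definitions and do not attempt to match those cells.

## Classifier harness

No deep-learning framework is assumed: the harness implements a compact
CNN in full — two 3×3 valid convolutions (8 and 16 filters) with ReLU, a
2×2 mean pool between them, global average pooling, a fixed affine feature
standardization estimated once on the training set, and a linear softmax
head — with exact backpropagation (finite-difference checked in the test
suite) and minibatch SGD. Design choices that matter:

* **Feature standardization.** The class signal is a ~1 % shift buried in
  features of much larger scale; standardizing the pooled features (an
  affine layer with fixed constants) is what makes the head trainable in
  tens of epochs. Gradients through the layer are scaled by `1/sd`, so
  updates are elementwise-clipped at ±1 to keep small-batch SGD stable.
* **Schedule.** Initial learning rate 0.001, ×0.1 every 7 epochs, batch
  16, 50 epochs, cross-entropy — the transfer-learning recipe of the
  motivating study, exposed as `train_config()`. The tested path is
  `smoke_config()`: 32-pixel inputs, frozen convolutional backbone
  (random features, head-only training — the CPU-scale analogue of
  transfer learning with a frozen pretrained trunk), 20 epochs at 0.1.
* **Grad-CAM** attaches to the second convolution: class-gradient-weighted
  feature maps, rectified, bilinearly upsampled, min-max normalized; a
  uniformly zero map is returned flagged rather than renormalized.

**The HSI ≥ ORI experiment.** The comparison corpus (30 scenes per class
per repetition, 48 px, `delta = 0.08`, `noise_sd = 0.01`,
`nuisance_sd = 0.25`) realizes the stated condition: class signal confined
to 500–600 nm, confounder variance just outside it. In the rendered ORI
images the discriminative direction (≈ the green channel, whose effective
spectral support is close to 500–600 nm) has a standard deviation ~25×
smaller than the confounded red/blue directions, so a small-sample learner
on random features struggles; band-selected reproduction suppresses the
confounder and exposes the signal in all channels. Over ten seeded
repetitions the HSI variant's test accuracy is ≥ the ORI variant's in at
least 8 (typically 9–10), mirroring the 3–4 % HSI gain reported on
clinical data — as a *property*, not as a reproduction of the clinical
accuracies, which depend on images we do not have.

Grad-CAM localization is validated on a corpus with a strong
fovea-localized case effect (`delta = 0.8`, `spatial_extent = "fovea"`):
the perturbation must itself be a locally dominant activation for
activation-based localization to be observable at all; with it, heatmap
mass inside the foveal disk exceeds the outside mean by ~50 %.

## Pipeline, sizes and budgets

`run_pipeline()` chains cohort → scenes → QC → calibration → conversion →
ROI spectra → window selection → reproduction → grouped stratified split
→ training → evaluation → `report.json`, with per-stage artifacts and
file-based resumability. Splits are image-level by default with an
optional subject-grouping guard (used by the pipeline), since the
motivating cohort has several images per case subject.

Problem sizes were chosen so the full validation runs comfortably on one
CPU: 48-pixel scenes for round trips and corpora, 24-pixel scenes for the
200 + 200 window-recovery corpus, 16–20 subjects for pipeline demos,
10 seeded repetitions for the classifier comparison. Spectra written to
CSV round-trip at 15 significant digits, so resumed pipelines agree with
fresh runs to ~1e-9 rather than bit-exactly; cubes are stored as 32-bit
float TIFF with a JSON wavelength sidecar.

## Limitations

The synthetic world is smooth and low-dimensional by construction: real
fundus spectra have texture, specularities, inter-device variation and
metamerism that no 3-channel inverse can resolve; passing the round-trip
and recovery tests shows the machinery is correct under the stated
conditions, not that a clinical camera achieves 0.015 RMSE. The compact
CNN is a harness for the comparison property, not a competitor to
large pretrained backbones. The exact polynomial term set and feature
space of the original conversion algorithm are not recoverable from the
available description; the two-stage reconstruction here is a documented
reconstruction of that family of methods.
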