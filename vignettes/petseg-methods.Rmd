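---
title: "Methods: automatic PET tumor-uptake segmentation with petseg"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: automatic PET tumor-uptake segmentation with petseg}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The problem

Delineating the functional tumor volume in FDG PET is a prerequisite both
for radiotherapy target definition and for radiomics pipelines, and it is
the step that still requires a human in the loop: classical PET segmentation
methods (thresholding, clustering, statistical models) are applied inside a
manually drawn volume of interest (VOI). In cervical cancer the need for a
VOI is acute, because the physiological uptake of the bladder sits directly
against the tumor and is typically as bright or brighter. `petseg`
implements a fully automatic alternative: a 3D convolutional network trained
end-to-end on whole-image patches, which must *learn* to separate tumor from
bladder without anatomical priors, together with everything needed to train
and evaluate it in a multi-center setting — a synthetic phantom cohort
generator, preprocessing, augmentation, training, sliding-window inference,
a fixed-threshold baseline, and a leave-one-center-out evaluation harness.

All network computation (3D convolutions, transposed convolutions, pooling,
instance normalization, squeeze-and-excitation gating, and the full backward
pass) is implemented inside the package in compiled code with a small
reverse-mode autodiff tape; no external deep-learning framework is used.

## The phantom generator

No public dataset exists with cervical-tumor PET volumes and bladder-aware
ground truth, so the package ships a generator that reproduces the
*statistical structure* the method is sensitive to, case by case:

* **Multi-center grids.** Each `center_profile()` carries a native voxel
  spacing, an in-plane matrix size and an axial-slice range. The full-scale
  profiles (`default_center_profiles()`) mirror a five-institution cohort of
  232 cases with spacings from 4.073 × 4.073 × 2.027 mm (Siemens Biograph)
  through 3.646 × 3.646 × 3.27 mm (GE Discovery) to 4 × 4 × 4 mm (Philips
  Gemini TF) and 77–192 axial slices.
* **Anatomy.** An ellipsoidal body of background uptake 1; a spherical
  bladder (radius 15–25 mm) in the anterior-inferior pelvis; a tumor
  ellipsoid with semiaxes 8–16 mm placed posterior-superior of the bladder.
  The tumor boundary can be lobulated by a smooth random field — real
  cervical tumors are not round, and shape priors are exactly what the
  method must not need.
* **The hard case by default.** The tumor-bladder surface gap is 0 mm
  (stuck) with probability 0.5 and otherwise uniform up to 3 mm, with the
  bladder 1.0–1.5 times as bright as the tumor (tumor-to-background uptake
  ratios 3–8, in the range of clinical SUV ratios). An adjacent, brighter
  bladder is the defining difficulty of this segmentation problem, so it is
  the generator's default condition rather than an option.
* **Image formation.** The ideal activity map (with a multiplicative
  heterogeneity field of amplitude up to 0.4 inside the tumor) is blurred
  with a Gaussian of 4.5 mm FWHM emulating PET partial-volume effects, then
  additive Gaussian noise (SD 5–12% of background) is applied and clipped at
  zero. Ground truth is the *pre-blur* ideal tumor support, analogous to
  ground truth defined independently of noise; as a consequence the truth
  boundary is systematically sharper than the image, and a perfect DSC of 1
  is not attainable even in principle.

What the phantoms do **not** emulate: sinogram-level physics and
reconstruction artifacts, attenuation, anatomical variability beyond
ellipsoids-with-lobulation, FIGO-stage structure, and non-bladder confounding
uptakes (bowel, kidneys). Passing the package's tests therefore demonstrates
that the pipeline works end to end under the stated statistical structure,
not that the trained desk-scale networks would transfer to clinical data.

```{r}
library(petseg)
cohort <- generate_cohort(desk_center_profiles(), seed = 42)
cohort
```

## Preprocessing

* **Common grid.** All volumes and masks are linearly interpolated to
  4 × 4 × 2 mm. The 2 mm slice keeps small axial detail. Resampling is
  node-centered (voxel *i* sits at `i * spacing`), with output shape
  `round((n-1) * s / t) + 1` per axis; this makes same-spacing resampling an
  exact identity and reproduces textbook 1D interpolation. Masks are
  interpolated linearly and re-binarized at 0.5 (nearest-neighbour is
  available behind a flag); the 0.5 threshold is a package decision, not an
  upstream fact.
* **Normalization.** Per-scan Z-scores computed from *non-zero* voxels only
  (the body); zero background voxels are transformed with the same affine
  map rather than pinned, which is the simplest consistent choice. The
  population SD is used, so a two-voxel body {1, 3} maps to {−1, +1}.
* **Patches.** Training samples are patches with uniformly random corners;
  volumes smaller than the patch are zero-padded (padding is neutral to the
  normalization because the statistics use non-zero voxels only). The
  full-scale patch is 128 × 128 × 64 voxels; the desk profile uses 16³–24³.

## Augmentation

Six stochastic transforms, each firing independently with probability 0.2,
in the fixed order mirror → affine → elastic → gamma → contrast → noise
(spatial before intensity, so intensity statistics stay interpretable; the
order is a package decision):

| transform | parameters (defaults) |
|---|---|
| axial mirror | in-plane flip |
| rotation + scale | angle U(5°, 15°) with random sign about a random non-empty axis subset; isotropic scale U(0.8, 1.2); performed in mm space |
| elastic | 4³ control grid, displacements U(−5, 5) mm, trilinear field |
| gamma | exponent U(0.8, 1.2) on intensities min-max mapped to [0, 1] and back — gamma is undefined on negative (Z-scored) values, so the unit remap is required |
| contrast stretch | range scaled by U(0.8, 1.2), anchored at the sample minimum (anchoring at 0 is meaningless after Z-scoring) |
| Gaussian noise | SD = U(0.1, 0.2) × patch SD |

Masks undergo the spatial transforms jointly with the image and are
re-binarized at 0.5; intensity transforms leave them untouched.

## Network

The proposed model is a 3D U-Net whose basic unit is a **full
pre-activation residual block**: instance-norm → ReLU → 3³ conv, twice, with
a **concurrent spatial and channel squeeze-and-excitation (scSE)** module on
the residual path and an identity (or 1³ projection) skip. Downsampling is
*learnable* — a strided 3³ convolution, instance norm, ReLU and scSE — with
a 7³ kernel in the very first (stem) block to enlarge the receptive field;
upsampling uses strided 3³ transposed convolutions, and decoder features are
concatenated with the encoder skip before a channel-reducing residual block.
A 1³ convolution plus sigmoid produces the voxelwise tumor probability.
Spatial dims are halved by the stem and at each encoder level, so inputs
must be divisible by `2^levels`.

Design points that were genuinely open and are fixed here as package
decisions:

* **Channel schedule** defaults to (24, 48, 96, 192) over 4 levels,
  configurable; the desk profile uses (6, 12, 24) over 3 levels.
* **scSE**: channel branch = global average pool → bottleneck (reduction 2)
  → sigmoid gate; spatial branch = 1³ conv → sigmoid gate; branches are
  *added* by default (`combine = "max"` available). Gate layers are
  zero-initialized, which makes every scSE module exactly the identity at
  initialization (both gates sit at 0.5 and the two halves sum back).
* **Instance norm** (ε = 1e-5, affine) rather than batch statistics — at
  batch size 2, and with the per-sample training loop used here, batch
  statistics degenerate to per-sample statistics anyway, so the StdU-Net
  baseline uses instance norm too.
* **Initialization**: Kaiming fan-in for convolutions; the head bias starts
  at −2 so that initial probabilities reflect the background-dominated class
  balance (≈ 0.12) instead of 0.5, which removes a wasteful early phase in
  which the Soft Dice loss must first unlearn a half-on prediction.
* **StdU-Net baseline**: same stem, depth and channels, but plain
  double-conv blocks, max pooling, and fixed trilinear 2× upsampling — the
  conventional reference architecture.

```{r}
model <- init_model(model_config("resunet"), seed = 1)
model          # parameter count
summary(model) # layer table
```

## Objective and training

The network minimizes the Soft Dice loss with Laplacian (+1) smoothing,

$$L(y, \hat y) = 1 - \frac{2\sum_i y_i \hat y_i + 1}
{\sum_i y_i^2 + \sum_i \hat y_i^2 + 1},$$

which is exactly 0 under perfect agreement (including the all-empty patch)
and bounded below 1. Optimization is Adam (β₁ = 0.9, β₂ = 0.99) under a
cosine annealing schedule from 1e-4 to 1e-6 with **warm restarts every 25
epochs** (16 restarts in the default 400 epochs), adjusted once per epoch;
reading the schedule as a single uninterrupted decay is available via
`restarts = FALSE`, and Adam moment estimates are carried across restarts.
Each epoch takes one patch per training case (configurable), in batches
of 2; per-sample losses and gradients are averaged. A center-stratified 20%
validation split is held out, validation is evaluated on deterministic
tumor-centered patches, and the checkpoint with the best validation DSC (at
threshold 0.5) is retained. Patch draws bias half the samples to contain
tumor — with desk-scale 16³–24³ patches an unbiased draw would rarely see
the lesion; at the full 128 × 128 × 64 patch size the bias is nearly
inconsequential since such patches almost always cover the tumor.

Everything is driven by R's RNG under a single seed: two runs with the same
seed produce bit-identical histories, parameters and predictions
(single-threaded deterministic kernels).

## Inference

Whole volumes are predicted by sliding windows of the training patch size
with 50% overlap and uniform averaging of overlapping probabilities (the
internal weight map is asserted positive everywhere); smaller volumes are
zero-padded and cropped back. Masks are produced at threshold 0.5. No
post-processing is applied by default — in particular no
largest-component or anatomical cleanup (a largest-component option exists
but is off). Predicted masks can be resampled back to the native grid
(linear + 0.5).

## Evaluation

* **Folds**: leave-one-center-out — each fold's test set is one entire
  center, the rest train (minus the validation split). Both networks are
  trained per fold from scratch with identical seeds and schedules, so only
  the architecture differs; the fixed-threshold baseline is evaluated on the
  same case lists.
* **T40 baseline**: threshold at 40% of the maximum uptake *within the
  tumor*. Emulated fully automatically, the threshold is searched over the
  entire volume (no VOI), so any structure brighter than 40% of the tumor
  peak — the bladder, by construction — is swept into the mask, which is
  precisely the failure mode that motivates learning-based delineation. A
  more charitable semi-localized variant (truth bounding box dilated by 2
  voxels, `t40_mode = "bbox"`) is available and reported alongside when
  used; on these phantoms it scores far higher, which is worth keeping in
  mind when comparing threshold baselines across papers: the *reported*
  performance of T40 is mostly a property of its regionalization.
* **Metrics**: per-case DSC, precision, recall from voxel confusion counts,
  with the conventions both-empty → 1 and one-empty → 0. Per-fold mean ± SD
  and a cross-fold average computed as the *unweighted* mean of fold means.
* **Stratified analysis**: rank-based decile groups by truth volume or by
  an *operational contrast* — tumor maximum over the mean of a 2-voxel
  peritumoral shell that excludes the bladder (the definition is
  package-local, chosen because it is computable on every case, and is
  recorded with the reports).
* **Outliers**: per-fold boxplot rule, DSC < Q1 − 1.5 IQR.
* **Method comparison**: paired Wilcoxon signed-rank plus two-sample
  Kolmogorov–Smirnov tests per metric (per fold and pooled) at α = 0.05;
  identical samples are reported as no difference.

```{r}
cohort <- preprocess_cohort(generate_cohort(desk_center_profiles(), seed = 42))
cv <- run_cv(cohort,
             models = list(proposed = model_config("resunet", levels = 3,
                                                   channels = c(6, 12, 24)),
                           stdunet = model_config("stdunet", levels = 3,
                                                  channels = c(6, 12, 24))),
             control = desk_train_config(epochs = 50, steps_per_epoch = 6,
                                         patch_size = c(24, 24, 24),
                                         cycle_epochs = 50),
             seed = 7)
cv_table(cv)
stratify(subset(cv$cases, method == "proposed"), by = "volume", n_groups = 5)
```

## Desk-scale profile

The package's tests and the acceptance script run the whole pipeline on one
CPU in minutes using `desk_train_config()` and `desk_center_profiles()`:
20 cases across 3 centers with 34–40 voxel in-plane matrices and 24–34
slices, 24³ training patches, networks of (6, 12, 24) channels over 3
levels, 50 epochs × 6 steps at batch 2 (600 patch gradients per model), and
a single cosine cycle from 3e-3 to 1e-4 — the higher rate compensating for
the short schedule. The single-phantom overfit check uses a 16³ phantom
(`desk_overfit_spec()`) and 300 optimizer steps. These sizes are the
package's chosen desk-scale study conditions; the full-scale defaults
(232 cases, 128 × 128 × 64 patches, 400 epochs) remain the configuration
defaults throughout.

## Numerical choices and degenerate inputs

* Resampling clamps out-of-range coordinates to the border (replicate).
* `znormalize()` refuses all-zero or constant-body scans with a classed
  degenerate-input error; `generate_phantom()` raises a placement error if
  the tumor cannot sit inside the body at the requested bladder gap (the
  cohort generator redraws geometry on such failures).
* Ties in decile stratification break by case id; quantiles use R's type 7.
* The Soft Dice gradient is computed analytically; all layer backward
  passes are verified against central finite differences in the test suite
  (relative tolerance 1e-2; observed agreement ≈ 1e-8).
* Wilcoxon tests use the normal approximation (`exact = FALSE`) for
  stability with ties; degenerate all-equal comparisons short-circuit to
  p = 1.

## Known limitations

* The phantom cohort is statistically, not anatomically, realistic; success
  here does not certify clinical performance.
* Desk-scale networks are small and briefly trained; their absolute DSC is
  well below what a full-scale run can reach, and single-fold orderings
  between the two CNN architectures can flip at this scale.
* Batch-level batch normalization is not implemented (instance norm
  everywhere), so the StdU-Net baseline is "standard" up to its norm layer.
* Training runs single-threaded; there is no GPU path.
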