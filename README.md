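# petseg

Fully automatic delineation of tumor functional uptake in 3D PET volumes,
built for the hardest everyday case in cervical-cancer imaging: a tumor
uptake sitting directly against the physiologically bright bladder, in
multi-center data with heterogeneous voxel grids. `petseg` provides the
entire pipeline in one R package — a synthetic multi-center phantom
generator with ground truth, preprocessing to a common grid, training-time
augmentation, a modified 3D U-Net (and a standard U-Net baseline) trained
with the Soft Dice loss, sliding-window inference, a fixed-threshold
baseline, and a leave-one-center-out cross-validation harness. All network
forward and backward passes are implemented in the package's own compiled
kernels; no external deep-learning framework is required.

## The model

The segmentation network is a 3D U-Net whose basic unit is a full
pre-activation residual block — IN → ReLU → conv(3³), twice — gated by a
concurrent spatial and channel squeeze-and-excitation (scSE) module on the
residual path. Max pooling is replaced by learnable downsampling (strided
3³ convolution + IN + ReLU + scSE; the first stem block uses a 7³ kernel),
and the decoder upsamples with 3³ transposed convolutions before
concatenating encoder skips. A 1³ convolution + sigmoid yields voxelwise
tumor probabilities p(x) ∈ (0,1).

Training minimizes the smoothed Soft Dice loss

    L(y, p) = 1 − (2 Σᵢ yᵢ pᵢ + 1) / (Σᵢ yᵢ² + Σᵢ pᵢ² + 1)

on randomly extracted, augmented patches (default 128×128×64, batch 2) with
Adam (β₁ = 0.9, β₂ = 0.99) and a cosine-annealed learning rate 10⁻⁴ → 10⁻⁶
restarting every 25 epochs. Evaluation reports DSC = 2PR/(P+R), precision P
and recall R per case, per held-out center, and as the unweighted cross-fold
average, against a T40 baseline (threshold at 40% of the maximum uptake
within the tumor).

## Worked example

```r
library(petseg)

# a 20-case, 3-center phantom cohort on heterogeneous native grids
cohort <- generate_cohort(desk_center_profiles(), seed = 42)
cohort
#> <petseg_cohort> 20 cases from 3 center(s)
#>   A: 6
#>   B: 7
#>   C: 7

# common 4x4x2 mm grid + body-only Z-scores
cohort <- preprocess_cohort(cohort)

# train the residual scSE U-Net on centers B and C, hold out center A
cases <- cohort$cases
fit <- petseg_fit(cases[grep("^A", names(cases), invert = TRUE)],
                  model = model_config("resunet", levels = 3,
                                       channels = c(6, 12, 24)),
                  control = desk_train_config(epochs = 50, steps_per_epoch = 6,
                                              patch_size = c(24, 24, 24),
                                              cycle_epochs = 50),
                  seed = 7)
fit
#> <petseg_fit> resunet, 50 epochs, 12 train / 2 val cases
#>   final train loss 0.1317; best val DSC 0.868

# predict the held-out center and score one case
cs <- cases[["A_001"]]
mask <- predict(fit, cs)
case_metrics(mask, cs$truth)
#> <case_metrics> DSC 0.763, precision 0.992, recall 0.620 (TP 248, FP 2, FN 152)

# the fully automatic fixed-threshold baseline on the same case
t40 <- t40_segment(cs$meta$raw_volume,
                   binary_mask3d(array(1, dim(cs$volume$values)),
                                 cs$volume$spacing),
                   threshold_region = cs$truth)
case_metrics(t40, cs$truth)$dsc
#> [1] 0.5072923
```

The trained network finds the tumor with only 2 false-positive voxels —
none of them in the adjacent bladder — while the threshold baseline,
lacking any notion of anatomy, sweeps the brighter bladder into its mask.
Across a full leave-one-center-out run of this cohort
(`run_cv(cohort, ...)`, six trainings; this is what the acceptance script
executes) the cross-fold average DSC is about 0.83 for the proposed
network, 0.79 for the standard U-Net and 0.30 for T40, whose precision
collapses to about 0.18 at recall near 1 — the qualitative failure of
fixed thresholding that motivates the learned approach. See the methods
vignette (`vignettes/petseg-methods.Rmd`) for the model, the phantom design
and every tunable default.

## Command-line use

A thin CLI over the same functions lives at `inst/cli/petseg.R`:

```sh
Rscript inst/cli/petseg.R phantom  --desk --seed 42 --out cohort/
Rscript inst/cli/petseg.R train    --desk --cohort cohort/ --out fit.rds
Rscript inst/cli/petseg.R predict  --fit fit.rds --cohort cohort/ --id A_001 --out mask.nii.gz
Rscript inst/cli/petseg.R evaluate --desk --cohort cohort/ --out metrics.csv
```
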