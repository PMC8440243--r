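# Soft Dice objective, per-case evaluation metrics and the T40
# fixed-threshold baseline.

#' Soft Dice loss
#'
#' For a binary target y and predicted probabilities p over N voxels,
#' `1 - (2 * sum(y * p) + 1) / (sum(y^2) + sum(p^2) + 1)`. The +1 Laplacian
#' smoothing terms keep the loss defined when a patch contains a single
#' class: perfect agreement (including the all-empty case) gives exactly 0.
#' The loss is bounded in \[0, 1).
#'
#' @param pred numeric array of probabilities in \[0, 1\].
#' @param target array with values in {0, 1}, same shape.
#' @return Scalar loss.
#' @export
soft_dice_loss <- function(pred, target) {
  if (!identical(dim(pred) %||% length(pred), dim(target) %||% length(target)))
    stop("`pred` and `target` must have the same shape")
  if (min(pred) < 0 || max(pred) > 1) stop("`pred` must be within [0, 1]")
  num <- 2 * sum(target * pred) + 1
  den <- sum(target^2) + sum(pred^2) + 1
  1 - num / den
}

# Gradient of soft_dice_loss w.r.t. pred.
soft_dice_grad <- function(pred, target) {
  num <- 2 * sum(target * pred) + 1
  den <- sum(target^2) + sum(pred^2) + 1
  -(2 * target * den - num * 2 * pred) / den^2
}

#' Per-case segmentation metrics
#'
#' Voxel confusion counts and the derived Dice similarity coefficient,
#' precision (positive predictive value) and recall (sensitivity), with
#' DSC = 2 TP / (2 TP + FP + FN), precision = TP / (TP + FP) and recall =
#' TP / (TP + FN); DSC is then the harmonic mean 2PR/(P+R). Edge
#' conventions: if both masks are empty, all three metrics are 1; if exactly
#' one is empty, all three are 0.
#'
#' @param pred_mask,truth_mask [binary_mask3d] objects (or plain {0,1}
#'   arrays) on the same grid.
#' @return A list of class `case_metrics`: `dsc`, `precision`, `recall`,
#'   counts `tp`, `fp`, `fn`, `truth_voxels`, and `truth_volume_cm3` when
#'   spacing is known.
#' @export
case_metrics <- function(pred_mask, truth_mask) {
  spacing <- NULL
  p <- if (inherits(pred_mask, "binary_mask3d")) pred_mask$values else pred_mask
  t_ <- if (inherits(truth_mask, "binary_mask3d")) {
    spacing <- truth_mask$spacing
    truth_mask$values
  } else truth_mask
  if (!identical(dim(p), dim(t_))) stop("masks must share a grid")
  p <- p != 0; t_ <- t_ != 0
  tp <- sum(p & t_); fp <- sum(p & !t_); fn <- sum(!p & t_)
  if (tp + fp + fn == 0) {
    dsc <- precision <- recall <- 1
  } else if (tp == 0 && (fp == 0 || fn == 0)) {
    dsc <- precision <- recall <- 0
  } else {
    precision <- if (tp + fp > 0) tp / (tp + fp) else 0
    recall <- if (tp + fn > 0) tp / (tp + fn) else 0
    dsc <- 2 * tp / (2 * tp + fp + fn)
  }
  structure(list(dsc = dsc, precision = precision, recall = recall,
                 tp = tp, fp = fp, fn = fn, truth_voxels = sum(t_),
                 truth_volume_cm3 = if (is.null(spacing)) NA_real_ else
                   sum(t_) * prod(spacing) / 1000),
            class = "case_metrics")
}

#' @export
print.case_metrics <- function(x, ...) {
  cat(sprintf("<case_metrics> DSC %.3f, precision %.3f, recall %.3f (TP %d, FP %d, FN %d)\n",
              x$dsc, x$precision, x$recall, x$tp, x$fp, x$fn))
  invisible(x)
}

#' Fixed-threshold segmentation at 40% of maximum uptake (T40)
#'
#' Thresholds the volume at `threshold_frac` (default 0.40) of the maximum
#' intensity within a search region and returns the voxels of that region at
#' or above the threshold. Scaling all intensities by a positive constant
#' leaves the result unchanged. When emulating a fully automatic baseline,
#' the search region is typically the ground-truth bounding box dilated by a
#' couple of voxels (see [t40_region()]); a brighter structure inside the
#' region (such as the bladder) then drives the threshold and degrades the
#' segmentation, which is the known failure mode of fixed thresholding.
#'
#' @param volume a [volume3d] of raw (non-normalized) uptake.
#' @param region a [binary_mask3d], the non-empty search region.
#' @param threshold_frac fraction of the reference maximum.
#' @param threshold_region optional [binary_mask3d] from which the reference
#'   maximum is taken (e.g., the tumor itself, mirroring "40% of the maximum
#'   uptake within the tumor"); defaults to `region`.
#' @return A [binary_mask3d].
#' @export
t40_segment <- function(volume, region, threshold_frac = 0.4,
                        threshold_region = NULL) {
  stopifnot(inherits(volume, "volume3d"), inherits(region, "binary_mask3d"))
  if (!identical(dim(volume$values), dim(region$values)))
    stop("volume and region must share a grid")
  if (sum(region$values) == 0) stop("search region must be non-empty")
  inreg <- region$values != 0
  ref <- if (is.null(threshold_region)) inreg else {
    stopifnot(inherits(threshold_region, "binary_mask3d"))
    threshold_region$values != 0
  }
  if (!any(ref)) stop("threshold region must be non-empty")
  thr <- threshold_frac * max(volume$values[ref])
  binary_mask3d((inreg & volume$values >= thr) + 0, volume$spacing)
}

#' Search region for the automatic T40 baseline
#'
#' The ground-truth bounding box dilated by `dilate` voxels on every side
#' (clipped to the grid). A permissive region that may capture nearby bright
#' structures, emulating threshold-based delineation applied without a
#' hand-drawn volume of interest.
#'
#' @param truth a [binary_mask3d].
#' @param dilate voxels of isotropic box dilation.
#' @return A [binary_mask3d].
#' @export
t40_region <- function(truth, dilate = 2) {
  stopifnot(inherits(truth, "binary_mask3d"))
  idx <- which(truth$values != 0, arr.ind = TRUE)
  if (nrow(idx) == 0) stop("truth mask is empty")
  d <- dim(truth$values)
  lo <- pmax(apply(idx, 2, min) - dilate, 1)
  hi <- pmin(apply(idx, 2, max) + dilate, d)
  reg <- array(0, d)
  reg[lo[1]:hi[1], lo[2]:hi[2], lo[3]:hi[3]] <- 1
  binary_mask3d(reg, truth$spacing)
}

#' Operational tumor contrast
#'
#' Maximum intensity inside the tumor mask divided by the mean intensity in
#' a peritumoral shell (`shell` voxels of box dilation beyond the tumor),
#' excluding bladder voxels. Used to stratify evaluation results by lesion
#' conspicuity.
#'
#' @param volume a [volume3d] of raw uptake.
#' @param truth tumor [binary_mask3d].
#' @param bladder optional bladder [binary_mask3d] to exclude from the shell.
#' @param shell shell thickness in voxels.
#' @return Scalar contrast (>= 0); `NA` if the shell is empty.
#' @export
operational_contrast <- function(volume, truth, bladder = NULL, shell = 2) {
  stopifnot(inherits(volume, "volume3d"), inherits(truth, "binary_mask3d"))
  d <- dim(truth$values)
  dil <- .cpp_dilate_box(truth$values, as.integer(d), as.integer(shell))
  ring <- dil > 0 & truth$values == 0
  if (!is.null(bladder)) ring <- ring & bladder$values == 0
  if (!any(ring)) return(NA_real_)
  denom <- mean(volume$values[ring])
  if (denom <= 0) return(NA_real_)
  max(volume$values[truth$values != 0]) / denom
}
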