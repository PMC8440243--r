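# Preprocessing: resampling heterogeneous native grids to the common analysis
# grid, body-only Z-score normalization, patch extraction, voxel volumes.

resample_core <- function(values, spacing, target_spacing, method) {
  d <- dim(values)
  # Node-centered resampling: voxel i sits at world coordinate i * spacing
  # along each axis; the output grid spans the same physical extent with
  # round((n-1) * s / t) + 1 nodes.
  od <- pmax(1L, as.integer(round((d - 1) * spacing / target_spacing)) + 1L)
  ux <- (seq_len(od[1]) - 1) * target_spacing[1] / spacing[1]
  uy <- (seq_len(od[2]) - 1) * target_spacing[2] / spacing[2]
  uz <- (seq_len(od[3]) - 1) * target_spacing[3] / spacing[3]
  if (method == "nearest") {
    ux <- pmin(round(ux), d[1] - 1); uy <- pmin(round(uy), d[2] - 1)
    uz <- pmin(round(uz), d[3] - 1)
    out <- values[cbind(rep(ux, times = od[2] * od[3]) + 1,
                        rep(rep(uy, each = od[1]), times = od[3]) + 1,
                        rep(uz, each = od[1] * od[2]) + 1)]
  } else {
    cx <- rep(ux, times = od[2] * od[3])
    cy <- rep(rep(uy, each = od[1]), times = od[3])
    cz <- rep(uz, each = od[1] * od[2])
    out <- .cpp_sample_trilinear(as.numeric(values), as.integer(d), cx, cy, cz)
  }
  array(out, dim = od)
}

#' Resample a volume to a target voxel spacing
#'
#' Brings a volume from its native grid to a target grid (by default the
#' common analysis resolution used throughout the package, 4 x 4 x 2 mm) by
#' linear interpolation. The output grid is node-centered on the input grid
#' and spans the same physical extent, with
#' `round((n - 1) * native_spacing / target_spacing) + 1` voxels per axis
#' (minimum 1). Resampling a volume to its own spacing is the identity.
#'
#' @param v a [volume3d].
#' @param target_spacing numeric triple, mm (all > 0).
#' @param method `"linear"` (default) or `"nearest"`.
#' @return A [volume3d] on the target grid.
#' @export
resample_volume <- function(v, target_spacing, method = c("linear", "nearest")) {
  stopifnot(inherits(v, "volume3d"))
  method <- match.arg(method)
  target_spacing <- check_len3(target_spacing, "target_spacing")
  if (any(target_spacing <= 0)) stop("`target_spacing` must be strictly positive")
  volume3d(resample_core(v$values, v$spacing, target_spacing, method),
           target_spacing, v$origin)
}

#' Resample a binary mask to a target voxel spacing
#'
#' The {0,1} field is linearly interpolated, then re-binarized at
#' `threshold` (0.5 by default). Nearest-neighbour interpolation is available
#' behind the `method` flag.
#'
#' @param m a [binary_mask3d].
#' @param target_spacing numeric triple, mm.
#' @param threshold binarization threshold applied after linear interpolation.
#' @param method `"linear"` or `"nearest"`.
#' @return A [binary_mask3d] on the target grid.
#' @export
resample_mask <- function(m, target_spacing, threshold = 0.5,
                          method = c("linear", "nearest")) {
  stopifnot(inherits(m, "binary_mask3d"))
  method <- match.arg(method)
  target_spacing <- check_len3(target_spacing, "target_spacing")
  if (any(target_spacing <= 0)) stop("`target_spacing` must be strictly positive")
  f <- resample_core(m$values, m$spacing, target_spacing, method)
  if (method == "linear") f <- (f >= threshold) + 0
  binary_mask3d(array(f, dim(f)), target_spacing)
}

#' Body-only Z-score normalization
#'
#' Standardizes a PET scan using the mean and standard deviation of its
#' non-zero voxels only (the body region); zero-valued background voxels do
#' not contribute to the statistics but are transformed with the same affine
#' map. After normalization the non-zero-voxel population of the input has
#' mean 0 and SD 1.
#'
#' @param v a [volume3d] with at least two distinct non-zero intensities.
#' @return A normalized [volume3d].
#' @export
znormalize <- function(v) {
  stopifnot(inherits(v, "volume3d"))
  nz <- v$values[v$values != 0]
  if (length(nz) < 2)
    stop_petseg("fewer than two non-zero voxels", "petseg_degenerate_input")
  mu <- mean(nz)
  s <- sqrt(mean((nz - mu)^2))  # population SD: {1,3} maps to {-1,+1}
  if (s == 0)
    stop_petseg("non-zero voxels have zero standard deviation",
                "petseg_degenerate_input")
  volume3d((v$values - mu) / s, v$spacing, v$origin)
}

#' Extract a random training patch from a case
#'
#' Draws a patch of `patch_size` voxels with its minimum corner uniformly
#' distributed over all valid positions. Volumes smaller than the patch along
#' any axis are zero-padded (mask padded with 0) before extraction, so the
#' operation never fails. With `foreground_bias > 0`, that fraction of draws
#' is forced to contain at least one tumor voxel (off by default).
#'
#' @param case a [patient_case] (preprocessed to the analysis grid).
#' @param patch_size integer triple of voxels.
#' @param foreground_bias probability of forcing a tumor-containing patch.
#' @return A list of class `petseg_patch` with elements `volume` and `mask`
#'   (arrays of dim `patch_size`), `spacing`, `case_id` and the 0-based
#'   minimum-corner index `corner`.
#' @export
extract_patch <- function(case, patch_size, foreground_bias = 0) {
  stopifnot(inherits(case, "patient_case"))
  patch_size <- as.integer(check_len3(patch_size, "patch_size"))
  vol <- case$volume$values
  msk <- case$truth$values
  d <- dim(vol)
  pd <- pmax(d, patch_size)
  if (any(pd > d)) {
    pvol <- array(0, pd); pmsk <- array(0, pd)
    pvol[seq_len(d[1]), seq_len(d[2]), seq_len(d[3])] <- vol
    pmsk[seq_len(d[1]), seq_len(d[2]), seq_len(d[3])] <- msk
    vol <- pvol; msk <- pmsk; d <- pd
  }
  nmax <- d - patch_size + 1L
  draw_corner <- function() c(sample.int(nmax[1], 1), sample.int(nmax[2], 1),
                              sample.int(nmax[3], 1)) - 1L
  corner <- draw_corner()
  if (foreground_bias > 0 && runif(1) < foreground_bias) {
    for (i in 1:20) {
      sl <- lapply(1:3, function(a) corner[a] + seq_len(patch_size[a]))
      if (sum(msk[sl[[1]], sl[[2]], sl[[3]]]) > 0) break
      corner <- draw_corner()
    }
  }
  sl <- lapply(1:3, function(a) corner[a] + seq_len(patch_size[a]))
  structure(list(volume = vol[sl[[1]], sl[[2]], sl[[3]], drop = FALSE],
                 mask = msk[sl[[1]], sl[[2]], sl[[3]], drop = FALSE],
                 spacing = case$volume$spacing,
                 case_id = case$case_id, corner = corner),
            class = "petseg_patch")
}

#' Mask volume in cubic centimetres
#'
#' Voxel count times voxel volume: e.g., 200 voxels on the 4 x 4 x 2 mm grid
#' are 6.4 cm^3. Additive over disjoint masks.
#'
#' @param m a [binary_mask3d].
#' @return Volume in cm^3.
#' @export
mask_volume_cm3 <- function(m) {
  stopifnot(inherits(m, "binary_mask3d"))
  sum(m$values) * prod(m$spacing) / 1000
}

#' Preprocess a case to the common analysis grid
#'
#' Resamples the volume and its masks to `target_spacing` (linear
#' interpolation; masks re-binarized at 0.5) and applies body-only Z-score
#' normalization to the volume. The pre-normalization resampled volume is
#' kept alongside, since the T40 baseline thresholds raw uptake.
#'
#' @param case a [patient_case] on its native grid.
#' @param target_spacing common grid spacing in mm, default `c(4, 4, 2)`.
#' @return A [patient_case] on the common grid, with the normalized volume in
#'   `$volume` and the resampled raw uptake in `$meta$raw_volume`.
#' @export
preprocess_case <- function(case, target_spacing = c(4, 4, 2)) {
  stopifnot(inherits(case, "patient_case"))
  rv <- resample_volume(case$volume, target_spacing)
  truth <- resample_mask(case$truth, target_spacing)
  if (sum(truth$values) == 0) {
    # resampling must not erase the ground truth; keep its nearest voxel
    nn <- resample_mask(case$truth, target_spacing, method = "nearest")
    truth <- nn
  }
  bladder <- if (is.null(case$bladder)) NULL else
    resample_mask(case$bladder, target_spacing)
  if (!is.null(bladder)) bladder$values <- bladder$values * (1 - truth$values)
  meta <- case$meta
  meta$raw_volume <- rv
  meta$native_spacing <- case$volume$spacing
  meta$preprocessed <- TRUE
  patient_case(znormalize(rv), truth, bladder, case$center, case$case_id, meta)
}
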