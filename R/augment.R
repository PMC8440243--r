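# Stochastic training-time transforms. Every transform maps (image, mask)
# jointly, keeps the mask binary and the image finite, and is applied on a
# `petseg_patch`. The composite `augment()` fires each transform
# independently with its configured probability, spatial transforms before
# intensity transforms.

#' Augmentation configuration
#'
#' Probabilities and parameter ranges of the training-time transforms.
#' Defaults: every transform fires independently with probability 0.2;
#' rotation angles uniform in 5-15 degrees about a random subset of axes;
#' isotropic scaling uniform in 0.8-1.2; gamma exponent uniform in 0.8-1.2
#' (applied on intensities min-max mapped to \[0,1\] and mapped back);
#' contrast range scaled by a uniform 0.8-1.2 factor; additive Gaussian noise
#' with SD equal to 0.1-0.2 of the patch SD; elastic deformation from a
#' 4x4x4 control grid with at most 5 mm displacement.
#'
#' @param p_apply per-transform firing probability (scalar, recycled).
#' @param rotation_deg_range ordered pair, degrees.
#' @param scale_range ordered pair.
#' @param gamma_range ordered pair.
#' @param contrast_upper_range ordered pair.
#' @param noise_sd_range ordered pair, fraction of patch SD.
#' @param elastic_grid control points per axis.
#' @param elastic_max_mm maximum control-point displacement, mm.
#' @return An object of class `augment_config`.
#' @export
augment_config <- function(p_apply = 0.2,
                           rotation_deg_range = c(5, 15),
                           scale_range = c(0.8, 1.2),
                           gamma_range = c(0.8, 1.2),
                           contrast_upper_range = c(0.8, 1.2),
                           noise_sd_range = c(0.1, 0.2),
                           elastic_grid = 4,
                           elastic_max_mm = 5) {
  chk <- function(r, nm) {
    if (length(r) != 2 || r[1] > r[2]) stop(sprintf("`%s` must be ordered", nm))
    as.numeric(r)
  }
  if (any(p_apply < 0 | p_apply > 1)) stop("`p_apply` must be in [0, 1]")
  structure(list(p_apply = p_apply,
                 rotation_deg_range = chk(rotation_deg_range, "rotation_deg_range"),
                 scale_range = chk(scale_range, "scale_range"),
                 gamma_range = chk(gamma_range, "gamma_range"),
                 contrast_upper_range = chk(contrast_upper_range, "contrast_upper_range"),
                 noise_sd_range = chk(noise_sd_range, "noise_sd_range"),
                 elastic_grid = as.integer(elastic_grid),
                 elastic_max_mm = as.numeric(elastic_max_mm)),
            class = "augment_config")
}

as_patch <- function(volume, mask, spacing, template) {
  structure(list(volume = volume, mask = mask, spacing = spacing,
                 case_id = template$case_id, corner = template$corner),
            class = "petseg_patch")
}

#' Mirror a patch in the axial plane
#'
#' Flips image and mask along one in-plane axis (left-right by default).
#' An involution: applying it twice restores the patch.
#'
#' @param patch a `petseg_patch`.
#' @param axis 1 or 2, the in-plane axis to flip.
#' @return The mirrored patch.
#' @export
mirror_axial <- function(patch, axis = 1) {
  stopifnot(axis %in% c(1, 2))
  d <- dim(patch$volume)
  idx <- rev(seq_len(d[axis]))
  if (axis == 1) {
    patch$volume <- patch$volume[idx, , , drop = FALSE]
    patch$mask <- patch$mask[idx, , , drop = FALSE]
  } else {
    patch$volume <- patch$volume[, idx, , drop = FALSE]
    patch$mask <- patch$mask[, idx, , drop = FALSE]
  }
  patch
}

rot_axis_mat <- function(axis, theta) {
  c_ <- cos(theta); s_ <- sin(theta)
  R <- diag(3)
  ij <- switch(axis, `1` = c(2, 3), `2` = c(1, 3), `3` = c(1, 2))
  R[ij[1], ij[1]] <- c_; R[ij[2], ij[2]] <- c_
  R[ij[1], ij[2]] <- -s_; R[ij[2], ij[1]] <- s_
  R
}

#' Sample parameters for a random affine transform
#'
#' Each of the three axes is independently included with probability 0.5 (at
#' least one forced); for each included axis, a rotation angle is drawn
#' uniformly from `rotation_deg_range` with a random sign; one isotropic
#' scale factor is drawn from `scale_range`.
#'
#' @param config an [augment_config].
#' @return A list with `axes` (integer vector), `angles_deg` (signed), and
#'   `scale`.
#' @export
sample_affine_params <- function(config = augment_config()) {
  axes <- which(runif(3) < 0.5)
  if (length(axes) == 0) axes <- sample.int(3, 1)
  angles <- runif(length(axes), config$rotation_deg_range[1],
                  config$rotation_deg_range[2]) *
    sample(c(-1, 1), length(axes), replace = TRUE)
  list(axes = axes, angles_deg = angles,
       scale = runif(1, config$scale_range[1], config$scale_range[2]))
}

warp_patch <- function(patch, coord_fun) {
  d <- dim(patch$volume)
  g <- grid_mm(d, patch$spacing)  # mm, centered on the patch
  cc <- coord_fun(g)
  # mm -> voxel node coordinates
  tox <- function(p, ax) p / patch$spacing[ax] + (d[ax] - 1) / 2
  cx <- tox(cc$x, 1); cy <- tox(cc$y, 2); cz <- tox(cc$z, 3)
  vol <- array(.cpp_sample_trilinear(patch$volume, as.integer(d),
                                     as.numeric(cx), as.numeric(cy), as.numeric(cz)), d)
  msk <- array(.cpp_sample_trilinear(patch$mask, as.integer(d),
                                     as.numeric(cx), as.numeric(cy), as.numeric(cz)), d)
  as_patch(vol, (msk >= 0.5) + 0, patch$spacing, patch)
}

#' Random rotation and scaling of a patch
#'
#' Rotates about the patch center (in mm space, so anisotropic voxels are
#' handled correctly) and scales isotropically; the image is linearly
#' interpolated, the mask re-binarized at 0.5. Regions mapped from outside
#' the patch are clamped to the border values.
#'
#' @param patch a `petseg_patch`.
#' @param config an [augment_config].
#' @param params optional pre-drawn parameters from [sample_affine_params()]
#'   (useful for reproducing a specific transform).
#' @return The transformed patch.
#' @export
random_affine <- function(patch, config = augment_config(), params = NULL) {
  if (is.null(params)) params <- sample_affine_params(config)
  R <- diag(3)
  for (k in seq_along(params$axes))
    R <- rot_axis_mat(params$axes[k], params$angles_deg[k] * pi / 180) %*% R
  Tinv <- t(R) / params$scale  # inverse of (R * scale)
  warp_patch(patch, function(g) {
    list(x = Tinv[1, 1] * g$x + Tinv[1, 2] * g$y + Tinv[1, 3] * g$z,
         y = Tinv[2, 1] * g$x + Tinv[2, 2] * g$y + Tinv[2, 3] * g$z,
         z = Tinv[3, 1] * g$x + Tinv[3, 2] * g$y + Tinv[3, 3] * g$z)
  })
}

#' Elastic deformation of a patch
#'
#' Displaces sampling coordinates by a smooth random field obtained by
#' trilinear interpolation of a coarse control grid
#' (`elastic_grid` points per axis) with i.i.d. uniform displacements bounded
#' by `elastic_max_mm`. Image and mask are warped jointly; the mask is
#' re-binarized. A zero displacement bound gives the identity.
#'
#' @inheritParams random_affine
#' @return The deformed patch.
#' @export
elastic_deform <- function(patch, config = augment_config()) {
  d <- dim(patch$volume)
  ng <- config$elastic_grid
  dmax <- config$elastic_max_mm
  if (dmax <= 0) return(patch)
  ctrl <- lapply(1:3, function(a) array(runif(ng^3, -dmax, dmax), c(ng, ng, ng)))
  # control-grid coordinates for each patch voxel
  ax <- lapply(1:3, function(a)
    if (d[a] == 1) rep(0, d[a]) else (seq_len(d[a]) - 1) / (d[a] - 1) * (ng - 1))
  cx <- rep(ax[[1]], times = d[2] * d[3])
  cy <- rep(rep(ax[[2]], each = d[1]), times = d[3])
  cz <- rep(ax[[3]], each = d[1] * d[2])
  disp <- lapply(ctrl, function(f)
    array(.cpp_sample_trilinear(f, as.integer(c(ng, ng, ng)), cx, cy, cz), d))
  warp_patch(patch, function(g)
    list(x = g$x + disp[[1]], y = g$y + disp[[2]], z = g$z + disp[[3]]))
}

#' Gamma correction of patch intensities
#'
#' Intensities are min-max mapped to \[0,1\], raised to a power gamma drawn
#' from `gamma_range`, and mapped back to the original range, so the
#' transform is well defined on Z-scored (negative) data and preserves the
#' intensity ordering. The mask is untouched.
#'
#' @inheritParams random_affine
#' @param gamma optional fixed exponent overriding the random draw.
#' @return The transformed patch.
#' @export
gamma_correct <- function(patch, config = augment_config(), gamma = NULL) {
  if (is.null(gamma))
    gamma <- runif(1, config$gamma_range[1], config$gamma_range[2])
  lo <- min(patch$volume); hi <- max(patch$volume)
  if (hi > lo)
    patch$volume <- lo + (hi - lo) * ((patch$volume - lo) / (hi - lo))^gamma
  patch
}

#' Contrast stretching of patch intensities
#'
#' Linearly rescales the intensity range so the new range is `c` times the
#' original, with `c` drawn from `contrast_upper_range`. The range is
#' anchored at the sample minimum. The mask is untouched.
#'
#' @inheritParams gamma_correct
#' @param factor optional fixed factor overriding the random draw.
#' @return The transformed patch.
#' @export
contrast_stretch <- function(patch, config = augment_config(), factor = NULL) {
  if (is.null(factor))
    factor <- runif(1, config$contrast_upper_range[1],
                    config$contrast_upper_range[2])
  lo <- min(patch$volume)
  patch$volume <- lo + (patch$volume - lo) * factor
  patch
}

#' Additive Gaussian noise
#'
#' Adds zero-mean Gaussian noise whose SD is a fraction (drawn from
#' `noise_sd_range`) of the patch's own intensity SD. The mask is untouched.
#'
#' @inheritParams gamma_correct
#' @param sd_fraction optional fixed fraction overriding the random draw.
#' @return The noisy patch.
#' @export
add_gaussian_noise <- function(patch, config = augment_config(),
                               sd_fraction = NULL) {
  if (is.null(sd_fraction))
    sd_fraction <- runif(1, config$noise_sd_range[1], config$noise_sd_range[2])
  s <- sd(patch$volume) * sd_fraction
  if (s > 0)
    patch$volume <- patch$volume + array(rnorm(length(patch$volume), 0, s),
                                         dim(patch$volume))
  patch
}

#' Apply the full augmentation pipeline
#'
#' Fires each transform independently with probability `p_apply`, in the
#' fixed order mirror, affine, elastic, gamma, contrast, noise (spatial
#' before intensity). With all probabilities 0 the patch is returned
#' bitwise-unchanged.
#'
#' @inheritParams random_affine
#' @return The augmented patch, with a logical attribute `"applied"` naming
#'   the transforms that fired.
#' @export
augment <- function(patch, config = augment_config()) {
  p <- rep(config$p_apply, length.out = 6)
  names(p) <- c("mirror", "affine", "elastic", "gamma", "contrast", "noise")
  fired <- runif(6) < p
  names(fired) <- names(p)
  if (fired["mirror"])   patch <- mirror_axial(patch)
  if (fired["affine"])   patch <- random_affine(patch, config)
  if (fired["elastic"])  patch <- elastic_deform(patch, config)
  if (fired["gamma"])    patch <- gamma_correct(patch, config)
  if (fired["contrast"]) patch <- contrast_stretch(patch, config)
  if (fired["noise"])    patch <- add_gaussian_noise(patch, config)
  attr(patch, "applied") <- fired
  patch
}
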