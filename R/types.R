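#' 3D PET volume with voxel spacing
#'
#' A minimal container for a scalar 3D intensity grid together with its voxel
#' spacing in millimetres and a world-space origin. Intensities are in
#' arbitrary uptake units (phantoms) or SUV-like units (clinical data).
#'
#' @param values numeric 3D array of intensities.
#' @param spacing numeric triple, voxel spacing in mm (all > 0).
#' @param origin numeric triple, world coordinates of voxel (0,0,0) in mm.
#' @return An object of class `volume3d`.
#' @export
volume3d <- function(values, spacing, origin = c(0, 0, 0)) {
  if (!is.array(values) || length(dim(values)) != 3)
    stop("`values` must be a 3D array")
  spacing <- check_len3(spacing, "spacing")
  if (any(spacing <= 0)) stop("`spacing` must be strictly positive")
  if (any(!is.finite(values))) stop("`values` must be finite")
  structure(list(values = values, spacing = spacing,
                 origin = check_len3(origin, "origin")),
            class = "volume3d")
}

#' Binary 3D mask aligned with a volume
#'
#' @param values array with values in {0, 1} (logical arrays are coerced).
#' @param spacing numeric triple, voxel spacing in mm.
#' @return An object of class `binary_mask3d`.
#' @export
binary_mask3d <- function(values, spacing) {
  if (!is.array(values) || length(dim(values)) != 3)
    stop("`values` must be a 3D array")
  if (is.logical(values)) values <- array(as.numeric(values), dim(values))
  if (!all(values %in% c(0, 1))) stop("mask values must be 0 or 1")
  spacing <- check_len3(spacing, "spacing")
  if (any(spacing <= 0)) stop("`spacing` must be strictly positive")
  structure(list(values = values, spacing = spacing), class = "binary_mask3d")
}

#' Patient case: volume, ground truth, center tag
#'
#' Bundles a PET volume with its ground-truth tumor mask, an optional bladder
#' mask (available for phantoms, where the generator knows it), the acquiring
#' center and a case identifier. All grids must share shape and spacing.
#'
#' @param volume a [volume3d].
#' @param truth a [binary_mask3d], the tumor ground truth (non-empty).
#' @param bladder optional [binary_mask3d], disjoint from `truth`.
#' @param center character scalar, acquiring center name.
#' @param case_id character scalar.
#' @param meta optional list of provenance (generator spec, draws).
#' @return An object of class `patient_case`.
#' @export
patient_case <- function(volume, truth, bladder = NULL, center, case_id,
                         meta = list()) {
  stopifnot(inherits(volume, "volume3d"), inherits(truth, "binary_mask3d"))
  if (!identical(dim(volume$values), dim(truth$values)) ||
      max(abs(volume$spacing - truth$spacing)) > 1e-6)
    stop_petseg("volume and truth mask are not on the same grid",
                "petseg_alignment_error")
  if (sum(truth$values) == 0) stop("ground-truth mask must be non-empty")
  if (!is.null(bladder)) {
    stopifnot(inherits(bladder, "binary_mask3d"))
    if (!identical(dim(volume$values), dim(bladder$values)))
      stop_petseg("bladder mask shape differs from volume",
                  "petseg_alignment_error")
    if (sum(truth$values * bladder$values) > 0)
      stop("truth and bladder masks must be disjoint")
  }
  structure(list(volume = volume, truth = truth, bladder = bladder,
                 center = as.character(center), case_id = as.character(case_id),
                 meta = meta),
            class = "patient_case")
}

#' @export
print.volume3d <- function(x, ...) {
  d <- dim(x$values)
  cat(sprintf("<volume3d> %d x %d x %d voxels @ %.3f x %.3f x %.3f mm\n",
              d[1], d[2], d[3], x$spacing[1], x$spacing[2], x$spacing[3]))
  cat(sprintf("  intensity range [%.3g, %.3g]\n",
              min(x$values), max(x$values)))
  invisible(x)
}

#' @export
print.binary_mask3d <- function(x, ...) {
  d <- dim(x$values)
  cat(sprintf("<binary_mask3d> %d x %d x %d voxels @ %.3f x %.3f x %.3f mm, %d foreground\n",
              d[1], d[2], d[3], x$spacing[1], x$spacing[2], x$spacing[3],
              as.integer(sum(x$values))))
  invisible(x)
}

#' @export
print.patient_case <- function(x, ...) {
  cat(sprintf("<patient_case> %s (center: %s)\n", x$case_id, x$center))
  print(x$volume)
  cat(sprintf("  tumor: %d voxels (%.2f cm^3)%s\n",
              as.integer(sum(x$truth$values)), mask_volume_cm3(x$truth),
              if (is.null(x$bladder)) "" else
                sprintf("; bladder: %d voxels", as.integer(sum(x$bladder$values)))))
  invisible(x)
}
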