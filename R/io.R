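# NIfTI input/output for cases and cohorts, plus the CSV cohort manifest.

nifti_spacing <- function(img) as.numeric(RNifti::pixdim(img))[1:3]

write_nifti3d <- function(values, spacing, path) {
  img <- RNifti::asNifti(values)
  RNifti::pixdim(img) <- spacing
  RNifti::writeNifti(img, path)
  invisible(path)
}

read_nifti3d <- function(path) {
  img <- RNifti::readNifti(path)
  list(values = array(as.numeric(img), dim(img)), spacing = nifti_spacing(img))
}

#' Write a case to NIfTI files
#'
#' Writes `<case_id>_pet.nii.gz`, `<case_id>_truth.nii.gz` and, when present,
#' `<case_id>_bladder.nii.gz` under `dir`, with the voxel spacing encoded in
#' the NIfTI header. Write-then-read round-trips preserve intensities, labels
#' and spacing to float precision.
#'
#' @param case a [patient_case].
#' @param dir output directory (created if needed).
#' @return Invisibly, the named vector of written paths.
#' @export
write_case <- function(case, dir) {
  stopifnot(inherits(case, "patient_case"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- c(pet = file.path(dir, paste0(case$case_id, "_pet.nii.gz")),
             truth = file.path(dir, paste0(case$case_id, "_truth.nii.gz")))
  write_nifti3d(case$volume$values, case$volume$spacing, paths[["pet"]])
  write_nifti3d(case$truth$values, case$truth$spacing, paths[["truth"]])
  if (!is.null(case$bladder)) {
    paths[["bladder"]] <- file.path(dir, paste0(case$case_id, "_bladder.nii.gz"))
    write_nifti3d(case$bladder$values, case$bladder$spacing, paths[["bladder"]])
  }
  invisible(paths)
}

#' Read a case from NIfTI files
#'
#' Counterpart of [write_case()]. Image and mask grids must agree in shape
#' and spacing (to 1e-4 mm); a mismatch raises an alignment error.
#'
#' @param dir directory holding the files.
#' @param case_id case identifier (file stem).
#' @param center center tag to attach (defaults to `"unknown"`).
#' @return A [patient_case].
#' @export
read_case <- function(dir, case_id, center = "unknown") {
  pet <- read_nifti3d(file.path(dir, paste0(case_id, "_pet.nii.gz")))
  truth <- read_nifti3d(file.path(dir, paste0(case_id, "_truth.nii.gz")))
  if (!identical(dim(pet$values), dim(truth$values)) ||
      max(abs(pet$spacing - truth$spacing)) > 1e-4)
    stop_petseg("image and mask grids do not align", "petseg_alignment_error")
  bpath <- file.path(dir, paste0(case_id, "_bladder.nii.gz"))
  bladder <- NULL
  if (file.exists(bpath)) {
    b <- read_nifti3d(bpath)
    if (!identical(dim(pet$values), dim(b$values)) ||
        max(abs(pet$spacing - b$spacing)) > 1e-4)
      stop_petseg("image and bladder mask grids do not align",
                  "petseg_alignment_error")
    bladder <- binary_mask3d((b$values >= 0.5) + 0, b$spacing)
  }
  patient_case(volume3d(pet$values, pet$spacing),
               binary_mask3d((truth$values >= 0.5) + 0, truth$spacing),
               bladder, center, case_id)
}

#' Write a cohort (NIfTI volumes + CSV manifest)
#'
#' @param cohort a [petseg_cohort].
#' @param dir output directory.
#' @return Invisibly, the manifest path.
#' @export
write_cohort <- function(cohort, dir) {
  stopifnot(inherits(cohort, "petseg_cohort"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  for (case in cohort$cases) write_case(case, dir)
  mpath <- file.path(dir, "manifest.csv")
  write.csv(cohort$manifest, mpath, row.names = FALSE)
  invisible(mpath)
}

#' Read a cohort written by [write_cohort()]
#'
#' Center assignment is restored from the manifest.
#'
#' @param dir directory holding the manifest and NIfTI files.
#' @return A [petseg_cohort].
#' @export
read_cohort <- function(dir) {
  manifest <- read.csv(file.path(dir, "manifest.csv"), stringsAsFactors = FALSE)
  cases <- list()
  for (i in seq_len(nrow(manifest))) {
    cid <- manifest$case_id[i]
    cases[[cid]] <- read_case(dir, cid, center = manifest$center[i])
  }
  structure(list(cases = cases, manifest = manifest), class = "petseg_cohort")
}
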