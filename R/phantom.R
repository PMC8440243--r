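# Synthetic multi-center PET phantom generator. Emulates the imaging context
# the segmentation method is built for: per-center voxel grids, variable
# axial extent, a tumor uptake adjacent to (possibly touching) a brighter
# bladder uptake, tumor heterogeneity, partial-volume blurring and noise.

#' Specification of a single PET phantom
#'
#' Geometry is expressed in millimetres in a coordinate frame centered on the
#' grid. The body is an ellipsoid of `body_semiaxes`; the bladder a sphere;
#' the tumor an ellipsoid with optional lobulated boundary perturbation.
#' Uptake values are in arbitrary units relative to `background_uptake`.
#'
#' @param grid_shape integer triple, voxels per axis.
#' @param voxel_spacing numeric triple, mm.
#' @param body_semiaxes numeric triple, mm.
#' @param background_uptake body uptake level (> 0).
#' @param bladder_center,bladder_radius,bladder_uptake sphere parameters (mm,
#'   mm, uptake). `bladder_uptake >= tumor_uptake` is allowed (the hard case).
#' @param tumor_center,tumor_semiaxes,tumor_uptake ellipsoid parameters.
#'   `tumor_uptake` must exceed `background_uptake`.
#' @param tumor_heterogeneity amplitude in \[0, 1\] of a multiplicative smooth
#'   random field inside the tumor.
#' @param tumor_lobularity amplitude of a smooth boundary perturbation; 0
#'   gives an exact ellipsoid.
#' @param gap_mm minimum tumor-bladder surface distance; 0 means touching.
#' @param noise_sd additive Gaussian noise SD as a fraction of
#'   `background_uptake`.
#' @param pve_fwhm_mm full width at half maximum of the Gaussian blur that
#'   emulates scanner partial-volume effects (PET resolution is about
#'   4-5 mm); 0 disables it.
#' @param seed integer RNG seed; the phantom is a deterministic function of
#'   the spec.
#' @return An object of class `phantom_spec`.
#' @export
phantom_spec <- function(grid_shape = c(64, 64, 64),
                         voxel_spacing = c(4, 4, 4),
                         body_semiaxes = NULL,
                         background_uptake = 1,
                         bladder_center = NULL, bladder_radius = 20,
                         bladder_uptake = 6,
                         tumor_center = NULL,
                         tumor_semiaxes = c(14, 12, 14),
                         tumor_uptake = 5,
                         tumor_heterogeneity = 0.3,
                         tumor_lobularity = 0.2,
                         gap_mm = 2, noise_sd = 0.08,
                         pve_fwhm_mm = 4.5, seed = 1) {
  grid_shape <- as.integer(check_len3(grid_shape, "grid_shape"))
  voxel_spacing <- check_len3(voxel_spacing, "voxel_spacing")
  if (any(voxel_spacing <= 0)) stop("voxel_spacing must be positive")
  fov <- grid_shape * voxel_spacing
  if (is.null(body_semiaxes)) body_semiaxes <- c(0.44, 0.42, 0.55) * fov
  if (is.null(bladder_center))
    bladder_center <- c(0, -0.16 * fov[2], -0.14 * fov[3])
  if (is.null(tumor_center))
    tumor_center <- bladder_center + c(0, 0.6, 0.8) / sqrt(1) *
      (bladder_radius + gap_mm + max(tumor_semiaxes) + 2)
  spec <- list(grid_shape = grid_shape, voxel_spacing = voxel_spacing,
               body_semiaxes = check_len3(body_semiaxes, "body_semiaxes"),
               background_uptake = background_uptake,
               bladder_center = check_len3(bladder_center, "bladder_center"),
               bladder_radius = bladder_radius,
               bladder_uptake = bladder_uptake,
               tumor_center = check_len3(tumor_center, "tumor_center"),
               tumor_semiaxes = check_len3(tumor_semiaxes, "tumor_semiaxes"),
               tumor_uptake = tumor_uptake,
               tumor_heterogeneity = tumor_heterogeneity,
               tumor_lobularity = tumor_lobularity,
               gap_mm = gap_mm, noise_sd = noise_sd,
               pve_fwhm_mm = pve_fwhm_mm, seed = as.integer(seed))
  validate_phantom_spec(spec)
  structure(spec, class = "phantom_spec")
}

validate_phantom_spec <- function(s) {
  if (s$background_uptake < 0 || s$bladder_uptake < 0 || s$tumor_uptake < 0)
    stop("uptake values must be non-negative")
  if (s$tumor_uptake <= s$background_uptake)
    stop("tumor_uptake must exceed background_uptake")
  if (s$gap_mm < 0) stop("gap_mm must be >= 0")
  if (s$tumor_heterogeneity < 0 || s$tumor_heterogeneity > 1)
    stop("tumor_heterogeneity must be in [0, 1]")
  if (s$noise_sd < 0) stop("noise_sd must be >= 0")
  if (any(s$tumor_semiaxes <= 0) || s$bladder_radius <= 0 ||
      any(s$body_semiaxes <= 0))
    stop("geometric sizes must be positive")
  invisible(s)
}

# Smooth unit-SD random field on grid `d`, built by blurring white noise with
# a Gaussian of `sigma_vox` voxels.
smooth_field <- function(d, sigma_vox) {
  f <- .cpp_gauss_blur3d(array(rnorm(prod(d)), d), as.integer(d),
                         as.numeric(sigma_vox))
  s <- sd(f)
  if (s == 0) array(0, d) else (f - mean(f)) / s
}

#' Generate one PET phantom with ground truth
#'
#' Builds the ideal activity map (body background, bladder sphere, tumor
#' ellipsoid with optional lobulation and a multiplicative heterogeneity
#' field), blurs it with a Gaussian emulating partial-volume effects, adds
#' Gaussian noise and clips at zero. The ground-truth tumor mask is the
#' pre-blurring ideal tumor support, mirroring ground truth defined
#' independently of noise. The tumor support is carved to keep the requested
#' minimum surface distance to the bladder, so truth and bladder masks are
#' disjoint by construction; with `gap_mm = 0` they may touch.
#'
#' @param spec a [phantom_spec].
#' @return A [patient_case] with `volume`, `truth`, `bladder` and generator
#'   provenance in `$meta`. Deterministic for a fixed spec (including seed).
#' @export
generate_phantom <- function(spec) {
  stopifnot(inherits(spec, "phantom_spec"))
  validate_phantom_spec(spec)
  with_seed(spec$seed, {
    d <- spec$grid_shape
    sp <- spec$voxel_spacing
    g <- grid_mm(d, sp)

    body <- ((g$x / spec$body_semiaxes[1])^2 +
             (g$y / spec$body_semiaxes[2])^2 +
             (g$z / spec$body_semiaxes[3])^2) <= 1
    bl_dist <- sqrt((g$x - spec$bladder_center[1])^2 +
                    (g$y - spec$bladder_center[2])^2 +
                    (g$z - spec$bladder_center[3])^2)
    bladder <- bl_dist <= spec$bladder_radius

    # Push the tumor away from the bladder along the center line until the
    # requested surface gap is feasible; the support function of the
    # (lobulated) ellipsoid bounds its extent along that direction.
    tc <- spec$tumor_center
    dirv <- tc - spec$bladder_center
    dn <- sqrt(sum(dirv^2))
    if (dn < 1e-9) { dirv <- c(0, 0.6, 0.8); dn <- 1 }
    u <- dirv / dn
    text <- sqrt(sum((spec$tumor_semiaxes * u)^2)) * (1 + spec$tumor_lobularity)
    need <- spec$bladder_radius + spec$gap_mm + text
    if (dn < need) tc <- spec$bladder_center + u * need

    q <- sqrt(((g$x - tc[1]) / spec$tumor_semiaxes[1])^2 +
              ((g$y - tc[2]) / spec$tumor_semiaxes[2])^2 +
              ((g$z - tc[3]) / spec$tumor_semiaxes[3])^2)
    radius <- 1
    if (spec$tumor_lobularity > 0) {
      lob <- smooth_field(d, pmax(1, min(spec$tumor_semiaxes) / sp / 2))
      radius <- 1 + spec$tumor_lobularity * pmax(pmin(lob, 2), -2) / 2
    }
    tumor <- q <= radius
    # hard-enforce the surface gap (and hence disjointness) at voxel level
    tumor <- tumor & (bl_dist >= spec$bladder_radius + spec$gap_mm)
    if (!any(tumor))
      stop_petseg("tumor support is empty at the requested gap",
                  "petseg_placement_error")
    if (any(tumor & !body))
      stop_petseg("tumor placement infeasible inside body at requested gap",
                  "petseg_placement_error")

    het <- 1
    if (spec$tumor_heterogeneity > 0) {
      hf <- smooth_field(d, pmax(1, min(spec$tumor_semiaxes) / sp / 2))
      het <- pmax(1 + spec$tumor_heterogeneity * pmax(pmin(hf, 2), -2) / 2, 0.1)
    }

    act <- array(0, d)
    act[body] <- spec$background_uptake
    act[bladder & body] <- spec$bladder_uptake
    tval <- spec$tumor_uptake * het
    if (length(tval) > 1) act[tumor] <- tval[tumor] else act[tumor] <- tval

    if (spec$pve_fwhm_mm > 0) {
      sigma_vox <- spec$pve_fwhm_mm / 2.355 / sp
      act <- .cpp_gauss_blur3d(act, as.integer(d), sigma_vox)
    }
    if (spec$noise_sd > 0)
      act <- act + rnorm(prod(d), 0, spec$noise_sd * spec$background_uptake)
    act <- pmax(act, 0)
    act <- array(act, d)

    patient_case(
      volume = volume3d(act, sp),
      truth = binary_mask3d(tumor + 0, sp),
      bladder = binary_mask3d((bladder & body & !tumor) + 0, sp),
      center = "phantom", case_id = sprintf("phantom_%06d", spec$seed),
      meta = list(spec = spec, tumor_center_mm = tc,
                  contrast = spec$tumor_uptake / spec$background_uptake)
    )
  })
}

#' Acquisition-center profile for cohort generation
#'
#' Describes one center's grid geometry and noise level, from which
#' [generate_cohort()] draws cases. Defaults mirror clinical whole-pelvis
#' FDG PET: 128 x 128 in-plane matrices and 77-192 axial slices.
#'
#' @param name center name.
#' @param voxel_spacing numeric triple, mm (strictly positive).
#' @param n_cases number of cases to generate for this center.
#' @param axial_slices_range integer pair, inclusive range of axial slices.
#' @param noise_sd_range numeric pair, per-case noise SD fraction range.
#' @param matrix_size in-plane grid size in voxels.
#' @return An object of class `center_profile`.
#' @export
center_profile <- function(name, voxel_spacing, n_cases,
                           axial_slices_range = c(77, 192),
                           noise_sd_range = c(0.05, 0.12),
                           matrix_size = 128) {
  voxel_spacing <- check_len3(voxel_spacing, "voxel_spacing")
  if (any(voxel_spacing <= 0)) stop("voxel_spacing must be strictly positive")
  if (n_cases < 1) stop("n_cases must be >= 1")
  if (length(axial_slices_range) != 2 || diff(axial_slices_range) < 0 ||
      axial_slices_range[1] < 1)
    stop("axial_slices_range must be an ordered positive pair")
  if (length(noise_sd_range) != 2 || diff(noise_sd_range) < 0 ||
      noise_sd_range[1] < 0)
    stop("noise_sd_range must be an ordered non-negative pair")
  structure(list(name = as.character(name), voxel_spacing = voxel_spacing,
                 n_cases = as.integer(n_cases),
                 axial_slices_range = as.integer(axial_slices_range),
                 noise_sd_range = as.numeric(noise_sd_range),
                 matrix_size = as.integer(matrix_size)),
            class = "center_profile")
}

#' Default five-center cohort profiles
#'
#' The five institutions with their case counts and representative native
#' voxel grids (Siemens Biograph 4.073 x 4.073 x 2.027 mm, GE Discovery
#' 3.646 x 3.646 x 3.27 mm, Philips Gemini TF 4 x 4 x 4 mm), totalling 232
#' cases.
#'
#' @return A list of [center_profile] objects.
#' @export
default_center_profiles <- function() {
  list(
    center_profile("Brest",     c(4.073, 4.073, 2.027), 69),
    center_profile("Nantes",    c(4.073, 4.073, 2.027), 23),
    center_profile("Montreal",  c(3.646, 3.646, 3.27),  26),
    center_profile("Barcelona", c(4, 4, 4),             24),
    center_profile("Liege",     c(4, 4, 4),             90)
  )
}

#' Generate a multi-center phantom cohort
#'
#' Draws per-case anatomy and uptake from fixed distributions chosen to span
#' realistic cervical-cancer FDG PET: tumor-to-background uptake ratios of
#' 3-8, a bladder 1.0-1.5 times as bright as the tumor, tumor semiaxes of
#' 8-16 mm, and a tumor-bladder surface gap that is 0 (stuck to the
#' bladder) with probability 0.5 and otherwise uniform up to 3 mm. Each case is tagged with
#' its center and generated on that center's native grid.
#'
#' @param profiles list of [center_profile] objects (at least one).
#' @param seed integer seed governing all draws.
#' @return An object of class `petseg_cohort`: a list with `cases` (list of
#'   [patient_case]) and `manifest` (data frame with case_id, center, seed,
#'   tumor voxel count, nominal contrast and gap).
#' @export
generate_cohort <- function(profiles, seed = 1) {
  if (inherits(profiles, "center_profile")) profiles <- list(profiles)
  if (length(profiles) < 1) stop("need at least one center profile")
  stopifnot(all(vapply(profiles, inherits, TRUE, "center_profile")))
  with_seed(seed, {
    cases <- list()
    rows <- list()
    for (pf in profiles) {
      for (i in seq_len(pf$n_cases)) {
        case <- NULL
        spec <- NULL
        for (attempt in 1:25) {
          slices <- if (diff(pf$axial_slices_range) == 0) pf$axial_slices_range[1]
                    else sample(pf$axial_slices_range[1]:pf$axial_slices_range[2], 1)
          case_seed <- sample.int(2147483646L, 1)
          tum_sa <- runif(3, 8, 16)
          tum_up <- runif(1, 3, 8)
          blad_up <- tum_up * runif(1, 1.0, 1.5)
          gap <- if (runif(1) < 0.5) 0 else runif(1, 0, 3)
          het <- runif(1, 0, 0.4)
          lob <- runif(1, 0, 0.35)
          nsd <- runif(1, pf$noise_sd_range[1], pf$noise_sd_range[2])
          blad_r <- runif(1, 15, 25)
          gs <- c(pf$matrix_size, pf$matrix_size, slices)
          fov <- gs * pf$voxel_spacing
          blad_c <- c(runif(1, -0.05, 0.05) * fov[1],
                      -0.16 * fov[2] + runif(1, -10, 10),
                      -0.14 * fov[3] + runif(1, -8, 8))
          dirv <- c(runif(1, -0.4, 0.4), runif(1, 0.3, 1), runif(1, 0.2, 1))
          dirv <- dirv / sqrt(sum(dirv^2))
          text <- sqrt(sum((tum_sa * dirv)^2)) * (1 + lob)
          tum_c <- blad_c + dirv * (blad_r + gap + text + 2)
          spec <- phantom_spec(
            grid_shape = gs, voxel_spacing = pf$voxel_spacing,
            background_uptake = 1,
            bladder_center = blad_c, bladder_radius = blad_r,
            bladder_uptake = blad_up,
            tumor_center = tum_c, tumor_semiaxes = tum_sa, tumor_uptake = tum_up,
            tumor_heterogeneity = het, tumor_lobularity = lob,
            gap_mm = gap, noise_sd = nsd, seed = case_seed)
          case <- tryCatch(generate_phantom(spec),
                           petseg_placement_error = function(e) NULL)
          if (!is.null(case)) break
        }
        if (is.null(case)) generate_phantom(spec)  # propagate the error
        case$center <- pf$name
        case$case_id <- sprintf("%s_%03d", pf$name, i)
        cases[[case$case_id]] <- case
        rows[[case$case_id]] <- data.frame(
          case_id = case$case_id, center = pf$name, seed = case_seed,
          tumor_voxels = sum(case$truth$values),
          tumor_volume_cm3 = mask_volume_cm3(case$truth),
          contrast = tum_up, bladder_tumor_ratio = blad_up / tum_up,
          gap_mm = gap, noise_sd = nsd, stringsAsFactors = FALSE)
      }
    }
    structure(list(cases = cases, manifest = do.call(rbind, c(rows, list(make.row.names = FALSE)))),
              class = "petseg_cohort")
  })
}

#' @export
print.petseg_cohort <- function(x, ...) {
  tab <- table(x$manifest$center)
  cat(sprintf("<petseg_cohort> %d cases from %d center(s)\n",
              nrow(x$manifest), length(tab)))
  for (nm in names(tab)) cat(sprintf("  %s: %d\n", nm, tab[[nm]]))
  invisible(x)
}

#' Preprocess every case of a cohort to the common grid
#'
#' @param cohort a [petseg_cohort].
#' @param target_spacing common grid spacing in mm.
#' @return The cohort with all cases passed through [preprocess_case()].
#' @export
preprocess_cohort <- function(cohort, target_spacing = c(4, 4, 2)) {
  stopifnot(inherits(cohort, "petseg_cohort"))
  cohort$cases <- lapply(cohort$cases, preprocess_case, target_spacing = target_spacing)
  cohort
}

#' Desk-scale three-center profiles
#'
#' A small multi-center cohort (20 cases, three centers with heterogeneous
#' voxel grids and axial extents) sized so that a full leave-one-center-out
#' experiment, including network training, runs in minutes on one CPU. The
#' anatomy and uptake distributions are the same as in the full-scale
#' generator; only grid extents and case counts are reduced.
#'
#' @return A list of three [center_profile] objects.
#' @export
desk_center_profiles <- function() {
  list(
    center_profile("A", c(4.0, 4.0, 4.0), 6, axial_slices_range = c(26, 30),
                   noise_sd_range = c(0.05, 0.10), matrix_size = 36),
    center_profile("B", c(4.4, 4.4, 3.2), 7, axial_slices_range = c(28, 34),
                   noise_sd_range = c(0.06, 0.12), matrix_size = 34),
    center_profile("C", c(3.6, 3.6, 4.4), 7, axial_slices_range = c(24, 28),
                   noise_sd_range = c(0.05, 0.10), matrix_size = 40)
  )
}

#' Single-phantom overfit specification
#'
#' A phantom whose grid is exactly one 16 x 16 x 16 training patch on the
#' analysis spacing (4 x 4 x 2 mm), with a small tumor adjacent to a
#' brighter bladder. Used for the optimization sanity check: a network
#' trained on this single case must drive its training loss near zero within
#' a few hundred steps.
#'
#' @param seed integer seed.
#' @return A [phantom_spec].
#' @export
desk_overfit_spec <- function(seed = 11) {
  phantom_spec(grid_shape = c(16, 16, 16), voxel_spacing = c(4, 4, 2),
               bladder_center = c(0, -10, -4.5), bladder_radius = 7,
               bladder_uptake = 6,
               tumor_center = c(0, -0.4, 8.3), tumor_semiaxes = c(6, 5, 6),
               tumor_uptake = 5, tumor_heterogeneity = 0.2,
               tumor_lobularity = 0.15, gap_mm = 1, noise_sd = 0.05,
               seed = seed)
}
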