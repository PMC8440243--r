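# Phantom generator: determinism, mask geometry, cohort structure, file I/O.

small_spec <- function(seed = 3, ...) {
  phantom_spec(grid_shape = c(32, 32, 24), voxel_spacing = c(4, 4, 4),
               bladder_radius = 12, tumor_semiaxes = c(10, 9, 10),
               seed = seed, ...)
}

test_that("a phantom is a deterministic function of its spec", {
  a <- generate_phantom(small_spec())
  b <- generate_phantom(small_spec())
  expect_identical(a$volume$values, b$volume$values)
  expect_identical(a$truth$values, b$truth$values)
  expect_identical(a$bladder$values, b$bladder$values)
  # a different seed changes the noise realization
  c_ <- generate_phantom(small_spec(seed = 4))
  expect_false(identical(a$volume$values, c_$volume$values))
})

test_that("tumor and bladder masks are disjoint and can touch at gap 0", {
  cs <- generate_phantom(small_spec(gap_mm = 0, bladder_uptake = 5,
                                    tumor_uptake = 5, tumor_lobularity = 0))
  expect_equal(sum(cs$truth$values * cs$bladder$values), 0)
  # touching: some tumor voxel is within one voxel of a bladder voxel
  dil <- petseg:::.cpp_dilate_box(cs$truth$values, dim(cs$truth$values), 1L)
  expect_gt(sum(dil * cs$bladder$values), 0)
})

test_that("the noiseless homogeneous limit carries exactly the tumor uptake", {
  cs <- generate_phantom(small_spec(noise_sd = 0, tumor_heterogeneity = 0,
                                    tumor_lobularity = 0, pve_fwhm_mm = 0))
  vals <- cs$volume$values[cs$truth$values == 1]
  expect_true(all(vals == cs$meta$spec$tumor_uptake))
  expect_true(all(cs$volume$values >= 0))
})

test_that("tumor mean exceeds background mean and intensities are non-negative", {
  cs <- generate_phantom(small_spec())
  body_bg <- cs$volume$values[cs$truth$values == 0 & cs$bladder$values == 0 &
                                cs$volume$values > 0]
  expect_gt(mean(cs$volume$values[cs$truth$values == 1]), mean(body_bg))
  expect_true(all(cs$volume$values >= 0))
})

test_that("infeasible tumor placement raises a placement error", {
  expect_error(
    generate_phantom(small_spec(tumor_center = c(500, 500, 500))),
    class = "petseg_placement_error")
})

test_that("raising tumor uptake does not decrease the operational contrast", {
  specs <- lapply(c(3, 5, 8), function(u) small_spec(tumor_uptake = u))
  contrasts <- vapply(specs, function(s) {
    cs <- generate_phantom(s)
    operational_contrast(cs$volume, cs$truth, cs$bladder)
  }, 1.0)
  expect_true(all(diff(contrasts) >= 0))
})

test_that("cohorts honor per-center counts, spacings and tagging", {
  profiles <- list(
    center_profile("Xa", c(4.073, 4.073, 2.027), 2,
                   axial_slices_range = c(24, 28), matrix_size = 32),
    center_profile("Yb", c(4, 4, 4), 3,
                   axial_slices_range = c(20, 24), matrix_size = 32))
  coh <- generate_cohort(profiles, seed = 5)
  expect_s3_class(coh, "petseg_cohort")
  expect_equal(nrow(coh$manifest), 5)
  expect_equal(as.integer(table(coh$manifest$center)[c("Xa", "Yb")]), c(2L, 3L))
  sp1 <- coh$cases[["Xa_001"]]$volume$spacing
  sp2 <- coh$cases[["Yb_002"]]$volume$spacing
  expect_equal(sp1, c(4.073, 4.073, 2.027))
  expect_equal(sp2, c(4, 4, 4))
  expect_equal(coh$cases[["Yb_001"]]$center, "Yb")
  # deterministic under the cohort seed
  coh2 <- generate_cohort(profiles, seed = 5)
  expect_identical(coh$cases[["Xa_002"]]$volume$values,
                   coh2$cases[["Xa_002"]]$volume$values)
})

test_that("a one-profile one-case cohort works", {
  coh <- generate_cohort(center_profile("solo", c(4, 4, 4), 1,
                                        axial_slices_range = c(20, 20),
                                        matrix_size = 32), seed = 2)
  expect_equal(length(coh$cases), 1L)
})

test_that("the full-scale profiles mirror the five-institution cohort", {
  pf <- default_center_profiles()
  expect_equal(sum(vapply(pf, function(p) p$n_cases, 1L)), 232L)
  expect_equal(vapply(pf, function(p) p$name, ""),
               c("Brest", "Nantes", "Montreal", "Barcelona", "Liege"))
  expect_equal(pf[[1]]$voxel_spacing, c(4.073, 4.073, 2.027))
  expect_equal(pf[[4]]$voxel_spacing, c(4, 4, 4))
  for (p in pf) expect_equal(p$axial_slices_range, c(77L, 192L))
})

test_that("NIfTI write/read round-trips a case and detects misalignment", {
  dir <- withr::local_tempdir()
  cs <- generate_phantom(small_spec())
  write_case(cs, dir)
  back <- read_case(dir, cs$case_id, center = "phantom")
  expect_equal(back$volume$values, cs$volume$values, tolerance = 1e-6)
  expect_identical(back$truth$values, cs$truth$values)
  expect_identical(back$bladder$values, cs$bladder$values)
  expect_equal(back$volume$spacing, cs$volume$spacing, tolerance = 1e-6)
  # corrupt the truth spacing -> alignment error
  petseg:::write_nifti3d(cs$truth$values, cs$truth$spacing * 2,
                         file.path(dir, paste0(cs$case_id, "_truth.nii.gz")))
  expect_error(read_case(dir, cs$case_id), class = "petseg_alignment_error")
})

test_that("cohort manifest round-trip preserves center assignment", {
  dir <- withr::local_tempdir()
  profiles <- list(
    center_profile("P1", c(4, 4, 4), 2, axial_slices_range = c(20, 22),
                   matrix_size = 32),
    center_profile("P2", c(4.4, 4.4, 3.2), 1, axial_slices_range = c(20, 22),
                   matrix_size = 32))
  coh <- generate_cohort(profiles, seed = 8)
  write_cohort(coh, dir)
  back <- read_cohort(dir)
  expect_equal(vapply(back$cases, function(cs) cs$center, ""),
               vapply(coh$cases, function(cs) cs$center, ""))
  expect_equal(back$manifest$case_id, coh$manifest$case_id)
})
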