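# Resampling, normalization, patch extraction and voxel-volume conversions.

test_that("resampling to the native spacing is the identity", {
  set.seed(1)
  v <- volume3d(array(rnorm(7 * 6 * 5), c(7, 6, 5)), c(4.073, 4.073, 2.027))
  r <- resample_volume(v, v$spacing)
  expect_lt(max(abs(r$values - v$values)), 1e-6)
  expect_identical(dim(r$values), dim(v$values))
})

test_that("a 1D ramp at 2 mm resampled to 1 mm doubles its sampling", {
  v <- volume3d(array(c(0, 2, 4), c(3, 1, 1)), c(2, 1, 1))
  r <- resample_volume(v, c(1, 1, 1))
  expect_equal(dim(r$values), c(5L, 1L, 1L))
  expect_equal(as.numeric(r$values), c(0, 1, 2, 3, 4))
})

test_that("resampling agrees with a brute-force reference on smooth fields", {
  set.seed(42)
  d <- c(9, 8, 6)
  base <- array(rnorm(prod(d)), d)
  smooth <- petseg:::.cpp_gauss_blur3d(base, as.integer(d), c(1.5, 1.5, 1.5)) + 2
  spacing <- c(4.073, 4.073, 2.027)
  for (target in list(c(4, 4, 2), c(3, 5, 2.5), c(8, 8, 4))) {
    v <- volume3d(array(smooth, d), spacing)
    got <- resample_volume(v, target)$values
    want <- oracle_resample(array(smooth, d), spacing, target)
    expect_identical(dim(got), dim(want))
    expect_lt(max(abs(got - want)) / max(abs(want)), 1e-4)
  }
})

test_that("masks downsample geometrically and empty masks stay empty", {
  m <- binary_mask3d(array(1, c(10, 10, 10)), c(2, 2, 2))
  r <- resample_mask(m, c(4, 4, 4))
  expect_equal(dim(r$values), c(5L, 5L, 5L))
  expect_true(all(r$values == 1))
  e <- binary_mask3d(array(0, c(8, 8, 8)), c(4, 4, 4))
  expect_equal(sum(resample_mask(e, c(3, 5, 7))$values), 0)
  # identity spacing keeps the mask bitwise
  m2 <- binary_mask3d(array(as.numeric(rbinom(4 * 4 * 4, 1, 0.5)), c(4, 4, 4)),
                      c(4, 4, 2))
  expect_identical(resample_mask(m2, c(4, 4, 2))$values, m2$values)
})

test_that("Z-score normalization uses body voxels only", {
  vals <- array(0, c(4, 4, 4))
  vals[1, 1, 1] <- 1; vals[2, 1, 1] <- 3
  z <- znormalize(volume3d(vals, c(4, 4, 2)))
  expect_equal(sort(z$values[c(1, 2)]), c(-1, 1))
  # zero voxels are transformed with the same affine map, not pinned
  expect_equal(unique(as.numeric(z$values[-c(1, 2)])), -2)

  set.seed(9)
  cs <- generate_phantom(phantom_spec(grid_shape = c(24, 24, 20),
                                      voxel_spacing = c(4, 4, 4),
                                      bladder_radius = 10,
                                      tumor_semiaxes = c(8, 8, 8), seed = 1))
  z2 <- znormalize(cs$volume)
  nz <- z2$values[cs$volume$values != 0]
  expect_lt(abs(mean(nz)), 1e-6)
  expect_lt(abs(sqrt(mean((nz - mean(nz))^2)) - 1), 1e-6)
})

test_that("Z-score normalization is invariant to positive rescaling", {
  set.seed(3)
  vals <- array(rexp(6 * 6 * 6), c(6, 6, 6))
  v1 <- znormalize(volume3d(vals, c(4, 4, 2)))
  v2 <- znormalize(volume3d(vals * 7.3, c(4, 4, 2)))
  expect_equal(v1$values, v2$values, tolerance = 1e-12)
})

test_that("degenerate normalization inputs raise classed errors", {
  expect_error(znormalize(volume3d(array(0, c(4, 4, 4)), c(4, 4, 2))),
               class = "petseg_degenerate_input")
  const <- array(0, c(4, 4, 4)); const[1:8] <- 5
  expect_error(znormalize(volume3d(const, c(4, 4, 2))),
               class = "petseg_degenerate_input")
})

test_that("a patch-sized volume yields the whole volume at corner zero", {
  cs <- make_toy_case(c(8, 8, 8))
  p <- extract_patch(cs, c(8, 8, 8))
  expect_equal(p$corner, c(0L, 0L, 0L))
  expect_identical(p$volume, cs$volume$values)
  expect_identical(p$mask, cs$truth$values)
})

test_that("patch corners are uniform over valid positions", {
  cs <- make_toy_case(c(5, 5, 5))
  set.seed(11)
  corners <- replicate(4000, paste(extract_patch(cs, c(4, 4, 4))$corner,
                                   collapse = ","))
  counts <- table(corners)
  expect_equal(length(counts), 8L)  # 2^3 valid corners
  expect_gt(stats::chisq.test(counts)$p.value, 0.01)
  # reproducible under a fixed seed
  set.seed(7); a <- replicate(5, extract_patch(cs, c(4, 4, 4))$corner)
  set.seed(7); b <- replicate(5, extract_patch(cs, c(4, 4, 4))$corner)
  expect_identical(a, b)
})

test_that("small volumes are zero-padded to the patch size", {
  cs <- make_toy_case(c(5, 6, 4))
  p <- extract_patch(cs, c(8, 8, 8))
  expect_equal(dim(p$volume), c(8L, 8L, 8L))
  expect_equal(dim(p$mask), c(8L, 8L, 8L))
  expect_identical(p$volume[1:5, 1:6, 1:4], cs$volume$values)
  expect_true(all(p$volume[6:8, , ] == 0))
  expect_equal(sum(p$mask), sum(cs$truth$values))
})

test_that("mask volumes convert to cm^3 and are additive", {
  d <- c(10, 10, 10)
  m <- array(0, d); m[seq_len(200)] <- 1
  expect_equal(mask_volume_cm3(binary_mask3d(m, c(4, 4, 2))), 6.4)
  m2 <- array(0, c(15, 15, 10)); m2[seq_len(1160)] <- 1
  expect_equal(mask_volume_cm3(binary_mask3d(m2, c(4, 4, 2))), 37.12)
  expect_equal(mask_volume_cm3(binary_mask3d(array(0, d), c(4, 4, 2))), 0)
  # additivity over disjoint masks
  set.seed(2)
  a <- array(rbinom(prod(d), 1, 0.3), d)
  b <- array(rbinom(prod(d), 1, 0.3), d) * (1 - a)
  s <- c(3.646, 3.646, 3.27)
  expect_equal(mask_volume_cm3(binary_mask3d(a + b, s)),
               mask_volume_cm3(binary_mask3d(a, s)) +
                 mask_volume_cm3(binary_mask3d(b, s)))
})

test_that("preprocess_case lands on the common grid with body statistics", {
  cs <- generate_phantom(phantom_spec(grid_shape = c(24, 24, 16),
                                      voxel_spacing = c(4.4, 4.4, 3.2),
                                      bladder_radius = 10,
                                      tumor_semiaxes = c(8, 8, 8), seed = 2))
  pp <- preprocess_case(cs, c(4, 4, 2))
  expect_equal(pp$volume$spacing, c(4, 4, 2))
  expect_identical(dim(pp$volume$values), dim(pp$truth$values))
  expect_gt(sum(pp$truth$values), 0)
  expect_equal(sum(pp$truth$values * pp$bladder$values), 0)
  expect_true(isTRUE(pp$meta$preprocessed))
  expect_equal(pp$meta$raw_volume$spacing, c(4, 4, 2))
})
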