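# Training-time transforms: joint image/mask behavior, parameter
# distributions, firing rates.

test_that("axial mirroring is an involution that preserves mask volume", {
  p <- make_toy_patch(c(6, 5, 4))
  m <- mirror_axial(p)
  expect_equal(sum(m$mask), sum(p$mask))
  expect_identical(mirror_axial(m)$volume, p$volume)
  expect_identical(mirror_axial(m)$mask, p$mask)
  # symmetric input is unchanged
  sym <- p
  sym$volume <- (p$volume + p$volume[rev(seq_len(6)), , ]) / 2
  sym$mask <- array(0, dim(p$mask)); sym$mask[c(2, 5), 3, 2] <- 1
  ms <- mirror_axial(sym)
  expect_equal(ms$volume, sym$volume)
  expect_identical(ms$mask, sym$mask)
})

test_that("an identity affine transform reproduces the patch", {
  p <- make_toy_patch(c(8, 8, 8))
  out <- random_affine(p, params = list(axes = 1L, angles_deg = 0, scale = 1))
  expect_lt(max(abs(out$volume - p$volume)), 1e-6)
  expect_identical(out$mask, p$mask)
})

test_that("isotropic scaling grows a centered cube by the cube of the factor", {
  d <- c(25, 25, 25)
  msk <- array(0, d); msk[9:17, 9:17, 9:17] <- 1  # 9^3 cube
  p <- structure(list(volume = msk, mask = msk, spacing = c(1, 1, 1),
                      case_id = "cube", corner = c(0L, 0L, 0L)),
                 class = "petseg_patch")
  out <- random_affine(p, params = list(axes = 1L, angles_deg = 0, scale = 1.2))
  ratio <- sum(out$mask) / sum(p$mask)
  expect_lt(abs(ratio - 1.2^3), 0.1 * 1.2^3)
})

test_that("sampled rotation angles are uniform on the configured range", {
  set.seed(21)
  draws <- replicate(1000, abs(sample_affine_params()$angles_deg[1]))
  ks <- suppressWarnings(stats::ks.test(draws, "punif", 5, 15))
  expect_gt(ks$p.value, 0.01)
  # scale stays in range, at least one axis always selected
  ps <- replicate(200, sample_affine_params(), simplify = FALSE)
  expect_true(all(vapply(ps, function(x) x$scale, 1) >= 0.8))
  expect_true(all(vapply(ps, function(x) x$scale, 1) <= 1.2))
  expect_true(all(vapply(ps, function(x) length(x$axes) >= 1, TRUE)))
})

test_that("elastic deformation is identity at zero displacement and reproducible", {
  p <- make_toy_patch(c(10, 10, 8))
  cfg0 <- augment_config(elastic_max_mm = 0)
  expect_identical(elastic_deform(p, cfg0), p)
  cfg <- augment_config(elastic_max_mm = 3)
  set.seed(5); a <- elastic_deform(p, cfg)
  set.seed(5); b <- elastic_deform(p, cfg)
  expect_identical(a$volume, b$volume)
  expect_true(all(a$mask %in% c(0, 1)))
  expect_true(all(is.finite(a$volume)))
})

test_that("small elastic deformations keep a convex mask in one piece", {
  d <- c(14, 14, 14)
  msk <- array(0, d); msk[5:10, 5:10, 5:10] <- 1
  p <- structure(list(volume = msk + 0.1, mask = msk, spacing = c(1, 1, 1),
                      case_id = "cube", corner = c(0L, 0L, 0L)),
                 class = "petseg_patch")
  cfg <- augment_config(elastic_max_mm = 1.5)
  for (s in 1:5) {
    set.seed(s)
    out <- elastic_deform(p, cfg)
    # single connected component: largest component holds all foreground
    expect_equal(sum(petseg:::largest_cc(out$mask)), sum(out$mask))
  }
})

test_that("gamma correction is a monotone power law on the unit-mapped range", {
  p <- make_toy_patch(c(6, 6, 6))
  expect_equal(gamma_correct(p, gamma = 1)$volume, p$volume, tolerance = 1e-12)
  q <- p
  q$volume <- array(seq(0, 1, length.out = prod(dim(p$volume))), dim(p$volume))
  q$volume[3] <- 0.5
  out <- gamma_correct(q, gamma = 2)
  expect_equal(out$volume[3], 0.25, tolerance = 1e-12)
  # ordering preserved on arbitrary data
  o1 <- order(p$volume); o2 <- order(gamma_correct(p, gamma = 0.8)$volume)
  expect_identical(o1, o2)
  expect_identical(gamma_correct(p, gamma = 2)$mask, p$mask)
})

test_that("contrast stretching rescales the range by the drawn factor", {
  p <- make_toy_patch(c(6, 6, 6))
  expect_equal(contrast_stretch(p, factor = 1)$volume, p$volume,
               tolerance = 1e-12)
  out <- contrast_stretch(p, factor = 0.8)
  expect_equal(diff(range(out$volume)), 0.8 * diff(range(p$volume)),
               tolerance = 1e-6)
  expect_identical(order(out$volume), order(p$volume))
})

test_that("additive noise hits its target standard deviation", {
  p <- make_toy_patch(c(48, 48, 48))
  expect_identical(add_gaussian_noise(p, sd_fraction = 0), p)
  set.seed(13)
  out <- add_gaussian_noise(p, sd_fraction = 0.15)
  target <- 0.15 * sd(p$volume)
  expect_lt(abs(sd(out$volume - p$volume) - target) / target, 0.05)
  set.seed(4); a <- add_gaussian_noise(p, sd_fraction = 0.1)
  set.seed(4); b <- add_gaussian_noise(p, sd_fraction = 0.1)
  expect_identical(a$volume, b$volume)
})

test_that("the composite pipeline respects firing probabilities", {
  p <- make_toy_patch(c(3, 3, 3))
  # all probabilities zero: bitwise identity
  out <- augment(p, augment_config(p_apply = 0))
  expect_identical(out$volume, p$volume)
  expect_identical(out$mask, p$mask)

  # all transforms at p = 1 with identity parameter ranges (mirror disabled:
  # it has no identity parameterization)
  cfg_id <- augment_config(p_apply = c(0, 1, 1, 1, 1, 1),
                           rotation_deg_range = c(0, 0),
                           scale_range = c(1, 1), gamma_range = c(1, 1),
                           contrast_upper_range = c(1, 1),
                           noise_sd_range = c(0, 0), elastic_max_mm = 0)
  set.seed(2)
  out2 <- augment(p, cfg_id)
  expect_lt(max(abs(out2$volume - p$volume)), 1e-9)
  expect_identical(out2$mask, p$mask)

  set.seed(31)
  fired <- replicate(10000, attr(augment(p, augment_config(p_apply = 0.2,
                                                           elastic_max_mm = 0)),
                                 "applied"))
  rates <- rowMeans(fired)
  expect_true(all(abs(rates - 0.2) < 0.02))
})

test_that("every transform keeps the mask binary and the image finite", {
  p <- make_toy_patch(c(8, 8, 8))
  cfg <- augment_config()
  set.seed(6)
  for (f in list(mirror_axial,
                 function(q) random_affine(q, cfg),
                 function(q) elastic_deform(q, cfg),
                 function(q) gamma_correct(q, cfg),
                 function(q) contrast_stretch(q, cfg),
                 function(q) add_gaussian_noise(q, cfg))) {
    out <- f(p)
    expect_true(all(out$mask %in% c(0, 1)))
    expect_true(all(is.finite(out$volume)))
    expect_identical(dim(out$volume), dim(p$volume))
  }
})
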