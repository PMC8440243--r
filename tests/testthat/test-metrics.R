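# Soft Dice loss, confusion metrics, T40 baseline, operational contrast.

test_that("Soft Dice loss matches hand evaluations", {
  z <- array(0, c(2, 1, 1))
  expect_equal(soft_dice_loss(z, z), 0)
  k <- array(c(1, 1, 0, 1), c(4, 1, 1))
  expect_equal(soft_dice_loss(k, k), 0)
  expect_equal(soft_dice_loss(c(0.5, 0.5), c(1, 0)), 0.2, tolerance = 1e-12)
  expect_equal(soft_dice_loss(0, 1), 0.5, tolerance = 1e-12)
  expect_error(soft_dice_loss(c(0.5, 0.5), c(1, 0, 0)), "shape")
  expect_error(soft_dice_loss(c(1.5, 0), c(1, 0)), "0, 1")
})

test_that("Soft Dice loss is symmetric, bounded, and monotone toward the target", {
  set.seed(8)
  for (rep in 1:20) {
    y <- rbinom(50, 1, 0.4)
    yhat_bin <- rbinom(50, 1, 0.4)
    expect_equal(soft_dice_loss(yhat_bin, y), soft_dice_loss(y, yhat_bin))
    p <- runif(50)
    l <- soft_dice_loss(p, y)
    expect_gte(l, 0); expect_lt(l, 1)
    # move every coordinate a step toward the target: loss cannot increase
    p2 <- p + 0.3 * (y - p)
    expect_lte(soft_dice_loss(p2, y), l + 1e-12)
  }
})

test_that("1 - Soft Dice approaches DSC as the grid grows", {
  set.seed(9)
  n <- 1e6
  y <- rbinom(n, 1, 0.1)
  p <- ifelse(y == 1, rbinom(n, 1, 0.9), rbinom(n, 1, 0.02))
  cm <- oracle_confusion(p, y)
  dsc <- 2 * cm$tp / (2 * cm$tp + cm$fp + cm$fn)
  expect_lt(abs((1 - soft_dice_loss(p, y)) - dsc), 1e-5)
})

test_that("case metrics match hand counts and the harmonic-mean identity", {
  d <- c(3, 3, 1)
  truth <- array(0, d); truth[1:2] <- 1
  pred <- array(0, d); pred[1:4] <- 1
  cm <- case_metrics(pred, truth)
  expect_equal(cm$precision, 0.5)
  expect_equal(cm$recall, 1.0)
  expect_equal(cm$dsc, 2 / 3)
  full <- case_metrics(truth, truth)
  expect_equal(c(full$dsc, full$precision, full$recall), c(1, 1, 1))
})

test_that("case metrics agree with a brute-force confusion oracle", {
  set.seed(10)
  for (rep in 1:1000) {
    d <- c(4, 3, 2)
    pred <- array(rbinom(prod(d), 1, runif(1)), d)
    truth <- array(rbinom(prod(d), 1, runif(1)), d)
    cm <- case_metrics(pred, truth)
    oc <- oracle_confusion(pred, truth)
    expect_identical(c(cm$tp, cm$fp, cm$fn), c(oc$tp, oc$fp, oc$fn))
    if (cm$precision + cm$recall > 0)
      expect_equal(cm$dsc,
                   2 * cm$precision * cm$recall / (cm$precision + cm$recall),
                   tolerance = 1e-12)
  }
})

test_that("empty-mask conventions hold", {
  d <- c(2, 2, 2)
  e <- array(0, d); f <- array(0, d); f[1] <- 1
  both <- case_metrics(e, e)
  expect_equal(c(both$dsc, both$precision, both$recall), c(1, 1, 1))
  pe <- case_metrics(e, f)
  expect_equal(c(pe$dsc, pe$precision, pe$recall), c(0, 0, 0))
  te <- case_metrics(f, e)
  expect_equal(c(te$dsc, te$precision, te$recall), c(0, 0, 0))
})

test_that("T40 thresholds at 40% of the reference maximum", {
  v <- volume3d(array(c(10, 5, 3, 1), c(4, 1, 1)), c(4, 4, 2))
  reg <- binary_mask3d(array(c(1, 1, 1, 0), c(4, 1, 1)), c(4, 4, 2))
  m <- t40_segment(v, reg)
  expect_equal(as.numeric(m$values), c(1, 1, 0, 0))  # threshold 4.0
  # uniform region selects everything
  u <- volume3d(array(7, c(2, 2, 1)), c(4, 4, 2))
  ru <- binary_mask3d(array(1, c(2, 2, 1)), c(4, 4, 2))
  expect_equal(sum(t40_segment(u, ru)$values), 4)
  # scale invariance
  v2 <- volume3d(v$values * 13.7, v$spacing)
  expect_identical(t40_segment(v2, reg)$values, m$values)
  expect_error(t40_segment(v, binary_mask3d(array(0, c(4, 1, 1)), c(4, 4, 2))),
               "non-empty")
})

test_that("a brighter structure in the search region degrades T40", {
  # tumor max 5, bladder 10 inside the search region: threshold rides the
  # bladder and the bladder is swept into the mask
  vals <- array(1, c(6, 1, 1)); vals[1:2] <- 5; vals[4:5] <- 10
  v <- volume3d(vals, c(4, 4, 2))
  truth <- binary_mask3d(array(c(1, 1, 0, 0, 0, 0), c(6, 1, 1)), c(4, 4, 2))
  all_ <- binary_mask3d(array(1, c(6, 1, 1)), c(4, 4, 2))
  m <- t40_segment(v, all_, threshold_region = truth)  # threshold 2.0
  expect_equal(as.numeric(m$values), c(1, 1, 0, 1, 1, 0))
  expect_lt(case_metrics(m, truth)$precision, 1)
})

test_that("the T40 bounding-box region dilates the truth box", {
  truth <- array(0, c(8, 8, 8)); truth[4:5, 4:5, 4:5] <- 1
  reg <- t40_region(binary_mask3d(truth, c(4, 4, 2)), dilate = 2)
  idx <- which(reg$values != 0, arr.ind = TRUE)
  expect_equal(unname(apply(idx, 2, range)),
               matrix(c(2, 7, 2, 7, 2, 7), 2))
})

test_that("operational contrast compares tumor peak to its shell", {
  vals <- array(1, c(9, 9, 9))
  truth <- array(0, c(9, 9, 9)); truth[4:6, 4:6, 4:6] <- 1
  vals[truth == 1] <- 4
  v <- volume3d(vals, c(4, 4, 4))
  tm <- binary_mask3d(truth, c(4, 4, 4))
  expect_equal(operational_contrast(v, tm), 4)
  # excluding a bright bladder from the shell raises the contrast
  blad <- array(0, c(9, 9, 9)); blad[8:9, , ] <- 1
  vals2 <- vals; vals2[blad == 1] <- 20
  c_with <- operational_contrast(volume3d(vals2, c(4, 4, 4)), tm)
  c_excl <- operational_contrast(volume3d(vals2, c(4, 4, 4)), tm,
                                 binary_mask3d(blad, c(4, 4, 4)))
  expect_gt(c_excl, c_with)
})
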