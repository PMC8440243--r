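# Architecture contracts: scSE gate algebra, residual identity, shape
# arithmetic, parameter counting, differentiability.

ns <- asNamespace("petseg")

# run a standalone scSE module with given parameter overrides
run_scse <- function(x, C, reduction = 2, combine = "add", override = list()) {
  cfg <- model_config("resunet", levels = 2, channels = c(C, C),
                      scse_reduction = reduction, combine = combine)
  m <- init_model(cfg, seed = 1)
  for (nm in names(override)) m$params[[nm]][] <- override[[nm]]
  tape <- ns$tape_new()
  pn <- lapply(m$params, function(p) ns$nd_leaf(tape, p))
  xn <- ns$nd_leaf(tape, x)
  ns$f_scse(tape, pn, "enc1.se", xn, cfg)$value
}

test_that("scSE preserves shape and obeys its gate algebra", {
  set.seed(1)
  x <- array(rnorm(4 * 4 * 2 * 4), c(4, 4, 2, 4))
  # zero-initialized gate layers: both gates are sigmoid(0) = 0.5, and the
  # two branches sum back to the input in addition mode
  y0 <- run_scse(x, C = 4)
  expect_identical(dim(y0), dim(x))
  expect_equal(y0, x, tolerance = 1e-12)
  # bias trick: large positive gate biases force both gates to 1 -> 2x
  y1 <- run_scse(x, C = 4, override = list(enc1.se.cse.b2 = 50,
                                           enc1.se.sse.b = 50))
  expect_equal(y1, 2 * x, tolerance = 1e-6)
  # max combination with both gates at 1 returns x
  y2 <- run_scse(x, C = 4, combine = "max",
                 override = list(enc1.se.cse.b2 = 50, enc1.se.sse.b = 50))
  expect_equal(y2, x, tolerance = 1e-6)
})

test_that("scSE rejects channel counts the reduction does not divide", {
  expect_error(model_config("resunet", levels = 2, channels = c(3, 3),
                            scse_reduction = 2), "divide")
})

test_that("a residual block with zeroed convolutions is the identity", {
  cfg <- model_config("resunet", levels = 2, channels = c(4, 4))
  m <- init_model(cfg, seed = 2)
  for (nm in c("enc1.c1.W", "enc1.c1.b", "enc1.c2.W", "enc1.c2.b"))
    m$params[[nm]][] <- 0
  tape <- ns$tape_new()
  pn <- lapply(m$params, function(p) ns$nd_leaf(tape, p))
  set.seed(3)
  x <- array(rnorm(4 * 4 * 4 * 4), c(4, 4, 4, 4))
  y <- ns$f_resblock(tape, pn, "enc1", ns$nd_leaf(tape, x), cfg, proj = FALSE)
  expect_equal(y$value, x, tolerance = 1e-12)
})

test_that("the 7x7x7 stem halves 128x128x64 to 64x64x32", {
  cfg <- model_config("resunet", levels = 2, channels = c(2, 2))
  m <- init_model(cfg, seed = 1)
  tape <- ns$tape_new()
  w <- ns$nd_leaf(tape, m$params$stem.W)
  b <- ns$nd_leaf(tape, m$params$stem.b)
  x <- ns$nd_leaf(tape, array(0, c(128, 128, 64, 1)))
  y <- ns$nd_conv(tape, x, w, b, stride = 2L)
  expect_identical(dim(y$value)[1:3], c(64L, 64L, 32L))
})

test_that("down- and upsampling invert each other's spatial dims", {
  cfg <- model_config("resunet", levels = 2, channels = c(2, 4))
  m <- init_model(cfg, seed = 1)
  tape <- ns$tape_new()
  x <- ns$nd_leaf(tape, array(rnorm(32 * 32 * 16 * 2), c(32, 32, 16, 2)))
  dn <- ns$nd_conv(tape, x, ns$nd_leaf(tape, m$params$down2.W),
                   ns$nd_leaf(tape, m$params$down2.b), stride = 2L)
  expect_identical(dim(dn$value)[1:3], c(16L, 16L, 8L))
  up <- ns$nd_convT(tape, dn, ns$nd_leaf(tape, m$params$up1.W),
                    ns$nd_leaf(tape, m$params$up1.b))
  expect_identical(dim(up$value)[1:3], c(32L, 32L, 16L))
})

test_that("forward maps valid shapes to same-shape probability maps", {
  for (arch in c("resunet", "stdunet")) {
    m <- init_model(model_config(arch, levels = 2, channels = c(2, 4)),
                    seed = 4)
    for (d in list(c(8, 8, 8), c(12, 8, 16), c(16, 12, 8))) {
      p <- net_forward(m, array(rnorm(prod(d)), d))
      expect_identical(dim(p), as.integer(d))
      expect_true(all(p > 0 & p < 1))
    }
    expect_error(net_forward(m, array(0, c(10, 8, 8))),
                 class = "petseg_shape_error")
    expect_error(net_forward(m, array(0, c(10, 8, 8))), "pad")
  }
})

test_that("parameter counts match an independent layer-by-layer sum", {
  ch <- c(4, 8, 16); L <- 3; r <- 2; k <- 3; ks <- 7
  conv_n <- function(kk, ci, co) kk^3 * ci * co + co
  norm_n <- function(c_) 2 * c_
  scse_n <- function(c_) (c_ * (c_ %/% r) + c_ %/% r) +
    ((c_ %/% r) * c_ + c_) + conv_n(1, c_, 1)
  res_n <- function(ci, co) norm_n(ci) + conv_n(k, ci, co) + norm_n(co) +
    conv_n(k, co, co) + scse_n(co) + if (ci != co) conv_n(1, ci, co) else 0

  want_res <- conv_n(ks, 1, ch[1]) + norm_n(ch[1]) + scse_n(ch[1]) +  # stem
    res_n(ch[1], ch[1]) +
    conv_n(k, ch[1], ch[2]) + norm_n(ch[2]) + scse_n(ch[2]) + res_n(ch[2], ch[2]) +
    conv_n(k, ch[2], ch[3]) + norm_n(ch[3]) + scse_n(ch[3]) + res_n(ch[3], ch[3]) +
    (k^3 * ch[2] * ch[3] + ch[2]) + norm_n(ch[2]) + scse_n(ch[2]) +  # up2
    res_n(2 * ch[2], ch[2]) +
    (k^3 * ch[1] * ch[2] + ch[1]) + norm_n(ch[1]) + scse_n(ch[1]) +  # up1
    res_n(2 * ch[1], ch[1]) +
    (k^3 * ch[1] * ch[1] + ch[1]) + norm_n(ch[1]) + scse_n(ch[1]) +  # final
    conv_n(1, ch[1], 1)
  m <- init_model(model_config("resunet", levels = L, channels = ch), seed = 1)
  expect_identical(count_params(m), as.integer(want_res))

  plain_n <- function(ci, co) conv_n(k, ci, co) + norm_n(co) +
    conv_n(k, co, co) + norm_n(co)
  want_std <- conv_n(ks, 1, ch[1]) + norm_n(ch[1]) +
    plain_n(ch[1], ch[1]) + plain_n(ch[1], ch[2]) + plain_n(ch[2], ch[3]) +
    conv_n(k, ch[3], ch[2]) + norm_n(ch[2]) + plain_n(2 * ch[2], ch[2]) +
    conv_n(k, ch[2], ch[1]) + norm_n(ch[1]) + plain_n(2 * ch[1], ch[1]) +
    conv_n(k, ch[1], ch[1]) + norm_n(ch[1]) + conv_n(1, ch[1], 1)
  ms <- init_model(model_config("stdunet", levels = L, channels = ch), seed = 1)
  expect_identical(count_params(ms), as.integer(want_std))
})

test_that("every parameter receives a gradient and it matches finite differences", {
  set.seed(5)
  x <- array(rnorm(8 * 8 * 8), c(8, 8, 8))
  y <- array(rbinom(8 * 8 * 8, 1, 0.2), c(8, 8, 8))
  for (arch in c("resunet", "stdunet")) {
    m <- init_model(model_config(arch, levels = 2, channels = c(2, 4)),
                    seed = 6)
    g <- ns$net_graph(m, x, train = TRUE)
    pred <- array(g$out$value, dim(x))
    ns$backward(g$tape, g$out,
                array(ns$soft_dice_grad(pred, y), dim(g$out$value)))
    grads <- lapply(g$pn, function(nd) nd$grad)
    expect_true(all(!vapply(grads, is.null, TRUE)))
    expect_true(all(vapply(grads, function(gr) all(is.finite(gr)), TRUE)))

    loss_of <- function(mm) soft_dice_loss(net_forward(mm, x), y)
    for (nm in sample(names(m$params), 6)) {
      i <- sample(length(m$params[[nm]]), 1)
      eps <- 1e-5
      mp <- m; mp$params[[nm]][i] <- mp$params[[nm]][i] + eps
      mm_ <- m; mm_$params[[nm]][i] <- mm_$params[[nm]][i] - eps
      fd <- (loss_of(mp) - loss_of(mm_)) / (2 * eps)
      an <- grads[[nm]][i]
      expect_lt(abs(fd - an) / max(1e-6, abs(fd), abs(an)), 1e-2)
    }
  }
})

test_that("initialization is deterministic and the forward pass is pure", {
  m1 <- tiny_resunet(seed = 9)
  m2 <- tiny_resunet(seed = 9)
  expect_identical(m1$params, m2$params)
  x <- array(rnorm(8 * 8 * 8), c(8, 8, 8))
  expect_identical(net_forward(m1, x), net_forward(m1, x))
})
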