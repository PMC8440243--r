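# Network architectures. The proposed model is a 3D U-Net whose basic unit
# is a full pre-activation residual block (instance norm -> ReLU -> conv,
# twice) gated by a concurrent spatial and channel squeeze-and-excitation
# (scSE) module on the residual path; max pooling is replaced by learnable
# strided-convolution downsampling blocks (the first with a 7x7x7 kernel,
# right after the input) and upsampling uses 3x3x3 transposed convolutions.
# A standard U-Net baseline (plain conv blocks, max pooling, trilinear
# upsampling) is constructible from the same configuration.

#' Model configuration
#'
#' All architecture knobs. The per-level channel schedule is configurable;
#' the default (24, 48, 96, 192) doubles channels at each of 4 resolution
#' levels. Spatial dims are halved by the input stem and at each subsequent
#' encoder level, so valid inputs have spatial dims divisible by
#' `2^levels`.
#'
#' @param arch `"resunet"` (residual scSE U-Net, the proposed model) or
#'   `"stdunet"` (standard U-Net baseline).
#' @param in_channels input channels (1 for PET).
#' @param levels number of resolution levels (>= 2).
#' @param channels integer vector of length `levels`, positive and
#'   non-decreasing.
#' @param scse_reduction channel-bottleneck reduction ratio of the scSE
#'   module; must divide every entry of `channels`.
#' @param stem_kernel kernel size of the first downsampling block.
#' @param block_kernel kernel size inside residual/plain blocks.
#' @param norm_eps instance-normalization epsilon.
#' @param combine how the two scSE branches are merged: `"add"` (default)
#'   or `"max"`.
#' @return An object of class `model_config`.
#' @export
model_config <- function(arch = c("resunet", "stdunet"), in_channels = 1,
                         levels = 4, channels = c(24, 48, 96, 192),
                         scse_reduction = 2, stem_kernel = 7, block_kernel = 3,
                         norm_eps = 1e-5, combine = c("add", "max")) {
  arch <- match.arg(arch)
  combine <- match.arg(combine)
  levels <- as.integer(levels)
  channels <- as.integer(channels)
  if (levels < 2) stop("`levels` must be >= 2")
  if (length(channels) != levels) stop("`channels` must have one entry per level")
  if (any(channels <= 0) || any(diff(channels) < 0))
    stop("`channels` must be positive and non-decreasing")
  if (arch == "resunet" && any(channels %% scse_reduction != 0))
    stop("`scse_reduction` must divide every channel count")
  if (stem_kernel %% 2 == 0 || block_kernel %% 2 == 0)
    stop("kernel sizes must be odd")
  structure(list(arch = arch, in_channels = as.integer(in_channels),
                 levels = levels, channels = channels,
                 scse_reduction = as.integer(scse_reduction),
                 stem_kernel = as.integer(stem_kernel),
                 block_kernel = as.integer(block_kernel),
                 norm_eps = norm_eps, combine = combine),
            class = "model_config")
}

# ---- parameter specification ----------------------------------------------

# Returns a named list mapping parameter names to their dims. Naming: .W/.b
# convolution or dense weights and biases, .g/.be instance-norm gain and
# shift. Transposed-convolution weights keep convolution orientation
# (k,k,k,out,in).
arch_param_dims <- function(cfg) {
  ps <- list()
  add <- function(nm, d) ps[[nm]] <<- d
  conv <- function(pfx, k, ci, co) { add(paste0(pfx, ".W"), c(k, k, k, ci, co)); add(paste0(pfx, ".b"), co) }
  norm <- function(pfx, c_) { add(paste0(pfx, ".g"), c_); add(paste0(pfx, ".be"), c_) }
  scse <- function(pfx, c_) {
    cr <- c_ %/% cfg$scse_reduction
    add(paste0(pfx, ".cse.W1"), c(c_, cr)); add(paste0(pfx, ".cse.b1"), cr)
    add(paste0(pfx, ".cse.W2"), c(cr, c_)); add(paste0(pfx, ".cse.b2"), c_)
    conv(paste0(pfx, ".sse"), 1, c_, 1)
  }
  L <- cfg$levels; ch <- cfg$channels; k <- cfg$block_kernel
  if (cfg$arch == "resunet") {
    resblock <- function(pfx, ci, co) {
      norm(paste0(pfx, ".n1"), ci); conv(paste0(pfx, ".c1"), k, ci, co)
      norm(paste0(pfx, ".n2"), co); conv(paste0(pfx, ".c2"), k, co, co)
      scse(paste0(pfx, ".se"), co)
      if (ci != co) conv(paste0(pfx, ".proj"), 1, ci, co)
    }
    conv("stem", cfg$stem_kernel, cfg$in_channels, ch[1]); norm("stem.n", ch[1])
    scse("stem.se", ch[1])
    for (l in seq_len(L)) {
      if (l > 1) {
        conv(sprintf("down%d", l), k, ch[l - 1], ch[l])
        norm(sprintf("down%d.n", l), ch[l]); scse(sprintf("down%d.se", l), ch[l])
      }
      resblock(sprintf("enc%d", l), ch[l], ch[l])
    }
    for (l in rev(seq_len(L - 1))) {
      add(sprintf("up%d.W", l), c(k, k, k, ch[l], ch[l + 1]))
      add(sprintf("up%d.b", l), ch[l])
      norm(sprintf("up%d.n", l), ch[l]); scse(sprintf("up%d.se", l), ch[l])
      resblock(sprintf("dec%d", l), 2L * ch[l], ch[l])
    }
    add("final.W", c(k, k, k, ch[1], ch[1])); add("final.b", ch[1])
    norm("final.n", ch[1]); scse("final.se", ch[1])
    conv("head", 1, ch[1], 1)
  } else {
    conv("stem", cfg$stem_kernel, cfg$in_channels, ch[1]); norm("stem.n", ch[1])
    for (l in seq_len(L)) {
      ci <- if (l == 1) ch[1] else ch[l - 1]
      conv(sprintf("enc%d.c1", l), k, ci, ch[l]); norm(sprintf("enc%d.n1", l), ch[l])
      conv(sprintf("enc%d.c2", l), k, ch[l], ch[l]); norm(sprintf("enc%d.n2", l), ch[l])
    }
    for (l in rev(seq_len(L - 1))) {
      conv(sprintf("up%d.red", l), k, ch[l + 1], ch[l]); norm(sprintf("up%d.n", l), ch[l])
      conv(sprintf("dec%d.c1", l), k, 2L * ch[l], ch[l]); norm(sprintf("dec%d.n1", l), ch[l])
      conv(sprintf("dec%d.c2", l), k, ch[l], ch[l]); norm(sprintf("dec%d.n2", l), ch[l])
    }
    conv("final", k, ch[1], ch[1]); norm("final.n", ch[1])
    conv("head", 1, ch[1], 1)
  }
  ps
}

init_param <- function(name, d) {
  # background-prior head bias: voxels start near sigmoid(-2), reflecting
  # that tumor occupies a small fraction of any patch
  if (name == "head.b") return(rep(-2, d))
  if (grepl("\\.(g)$", name)) return(rep(1, d))
  if (grepl("\\.(b|be|b1|b2)$", name)) return(rep(0, d))
  # gate layers start at zero so every scSE module is the identity at
  # initialization (both gates sit at sigmoid(0) = 0.5 and the two branches
  # sum back to the input)
  if (grepl("(cse\\.W2|sse\\.W)$", name)) {
    if (length(d) > 1) return(array(0, d)) else return(rep(0, d))
  }
  if (length(d) == 2)  # dense
    return(array(rnorm(prod(d), 0, sqrt(2 / d[1])), d))
  fan_in <- prod(d[1:4])
  array(rnorm(prod(d), 0, sqrt(2 / fan_in)), d)
}

#' Initialize a model
#'
#' Kaiming fan-in initialization for convolutions, unit gain / zero shift for
#' instance norm, zero-initialized scSE gate layers (so gating starts at
#' the identity), and a -2 head bias so initial tumor probabilities reflect
#' the background-dominated class balance.
#'
#' @param config a [model_config].
#' @param seed integer RNG seed.
#' @return An object of class `petseg_model` holding the named parameter
#'   arrays.
#' @export
init_model <- function(config = model_config(), seed = 1) {
  dims <- arch_param_dims(config)
  params <- with_seed(seed, {
    ps <- vector("list", length(dims))
    names(ps) <- names(dims)
    for (nm in names(dims)) ps[[nm]] <- init_param(nm, dims[[nm]])
    ps
  })
  structure(list(config = config, params = params,
                 n_params = sum(vapply(params, length, 1L))),
            class = "petseg_model")
}

#' Count trainable parameters
#' @param model a `petseg_model`.
#' @return Integer parameter count.
#' @export
count_params <- function(model) sum(vapply(model$params, length, 1L))

#' @export
print.petseg_model <- function(x, ...) {
  cat(sprintf("<petseg_model> %s: %d levels, channels [%s], %s parameters\n",
              x$config$arch, x$config$levels,
              paste(x$config$channels, collapse = ", "),
              format(x$n_params, big.mark = ",")))
  invisible(x)
}

# ---- forward graphs --------------------------------------------------------

# Fetch-or-fail accessor over parameter nodes.
pget <- function(pn, nm) {
  nd <- pn[[nm]]
  if (is.null(nd)) stop(sprintf("internal: unknown parameter `%s`", nm))
  nd
}

f_scse <- function(tape, pn, pfx, x, cfg) {
  z <- nd_gap(tape, x)
  z <- nd_relu(tape, nd_dense(tape, z, pget(pn, paste0(pfx, ".cse.W1")),
                              pget(pn, paste0(pfx, ".cse.b1"))))
  gch <- nd_sigmoid(tape, nd_dense(tape, z, pget(pn, paste0(pfx, ".cse.W2")),
                                   pget(pn, paste0(pfx, ".cse.b2"))))
  xc <- nd_cmul(tape, x, gch)
  gsp <- nd_sigmoid(tape, nd_conv(tape, x, pget(pn, paste0(pfx, ".sse.W")),
                                  pget(pn, paste0(pfx, ".sse.b"))))
  xs <- nd_smul(tape, x, gsp)
  if (cfg$combine == "add") nd_add(tape, xc, xs) else nd_emax(tape, xc, xs)
}

f_norm_relu <- function(tape, pn, pfx, x, cfg) {
  nd_relu(tape, nd_inorm(tape, x, pget(pn, paste0(pfx, ".g")),
                         pget(pn, paste0(pfx, ".be")), cfg$norm_eps))
}

f_resblock <- function(tape, pn, pfx, x, cfg, proj) {
  h <- f_norm_relu(tape, pn, paste0(pfx, ".n1"), x, cfg)
  h <- nd_conv(tape, h, pget(pn, paste0(pfx, ".c1.W")), pget(pn, paste0(pfx, ".c1.b")))
  h <- f_norm_relu(tape, pn, paste0(pfx, ".n2"), h, cfg)
  h <- nd_conv(tape, h, pget(pn, paste0(pfx, ".c2.W")), pget(pn, paste0(pfx, ".c2.b")))
  h <- f_scse(tape, pn, paste0(pfx, ".se"), h, cfg)
  skip <- if (proj)
    nd_conv(tape, x, pget(pn, paste0(pfx, ".proj.W")), pget(pn, paste0(pfx, ".proj.b")))
  else x
  nd_add(tape, skip, h)
}

forward_resunet <- function(tape, pn, x, cfg) {
  L <- cfg$levels
  s <- nd_conv(tape, x, pget(pn, "stem.W"), pget(pn, "stem.b"), stride = 2L)
  s <- f_norm_relu(tape, pn, "stem.n", s, cfg)
  s <- f_scse(tape, pn, "stem.se", s, cfg)
  enc <- vector("list", L)
  h <- s
  for (l in seq_len(L)) {
    if (l > 1) {
      h <- nd_conv(tape, h, pget(pn, sprintf("down%d.W", l)),
                   pget(pn, sprintf("down%d.b", l)), stride = 2L)
      h <- f_norm_relu(tape, pn, sprintf("down%d.n", l), h, cfg)
      h <- f_scse(tape, pn, sprintf("down%d.se", l), h, cfg)
    }
    h <- f_resblock(tape, pn, sprintf("enc%d", l), h, cfg, proj = FALSE)
    enc[[l]] <- h
  }
  for (l in rev(seq_len(L - 1))) {
    h <- nd_convT(tape, h, pget(pn, sprintf("up%d.W", l)),
                  pget(pn, sprintf("up%d.b", l)))
    h <- f_norm_relu(tape, pn, sprintf("up%d.n", l), h, cfg)
    h <- f_scse(tape, pn, sprintf("up%d.se", l), h, cfg)
    h <- nd_concat(tape, h, enc[[l]])
    h <- f_resblock(tape, pn, sprintf("dec%d", l), h, cfg, proj = TRUE)
  }
  h <- nd_convT(tape, h, pget(pn, "final.W"), pget(pn, "final.b"))
  h <- f_norm_relu(tape, pn, "final.n", h, cfg)
  h <- f_scse(tape, pn, "final.se", h, cfg)
  h <- nd_conv(tape, h, pget(pn, "head.W"), pget(pn, "head.b"))
  nd_sigmoid(tape, h)
}

forward_stdunet <- function(tape, pn, x, cfg) {
  L <- cfg$levels
  plain <- function(pfx, h) {
    h <- nd_conv(tape, h, pget(pn, paste0(pfx, ".c1.W")), pget(pn, paste0(pfx, ".c1.b")))
    h <- f_norm_relu(tape, pn, paste0(pfx, ".n1"), h, cfg)
    h <- nd_conv(tape, h, pget(pn, paste0(pfx, ".c2.W")), pget(pn, paste0(pfx, ".c2.b")))
    f_norm_relu(tape, pn, paste0(pfx, ".n2"), h, cfg)
  }
  h <- nd_conv(tape, x, pget(pn, "stem.W"), pget(pn, "stem.b"), stride = 2L)
  h <- f_norm_relu(tape, pn, "stem.n", h, cfg)
  enc <- vector("list", L)
  for (l in seq_len(L)) {
    if (l > 1) h <- nd_maxpool(tape, h)
    h <- plain(sprintf("enc%d", l), h)
    enc[[l]] <- h
  }
  for (l in rev(seq_len(L - 1))) {
    h <- nd_upsample2x(tape, h)
    h <- nd_conv(tape, h, pget(pn, sprintf("up%d.red.W", l)),
                 pget(pn, sprintf("up%d.red.b", l)))
    h <- f_norm_relu(tape, pn, sprintf("up%d.n", l), h, cfg)
    h <- nd_concat(tape, h, enc[[l]])
    h <- plain(sprintf("dec%d", l), h)
  }
  h <- nd_upsample2x(tape, h)
  h <- nd_conv(tape, h, pget(pn, "final.W"), pget(pn, "final.b"))
  h <- f_norm_relu(tape, pn, "final.n", h, cfg)
  h <- nd_conv(tape, h, pget(pn, "head.W"), pget(pn, "head.b"))
  nd_sigmoid(tape, h)
}

check_input_dims <- function(d, cfg) {
  div <- 2^cfg$levels
  if (any(d[1:3] %% div != 0)) {
    pad <- (div - d[1:3] %% div) %% div
    stop_petseg(sprintf(
      "spatial dims (%s) must be divisible by %d; pad by (%s) voxels",
      paste(d[1:3], collapse = "x"), div, paste(pad, collapse = ",")),
      "petseg_shape_error")
  }
}

# Build the forward graph. Returns the tape, output node and parameter nodes.
net_graph <- function(model, x_array, train = FALSE) {
  cfg <- model$config
  if (length(dim(x_array)) == 3)
    x_array <- array(x_array, c(dim(x_array), 1L))
  d <- dim4(x_array)
  check_input_dims(d, cfg)
  if (d[4] != cfg$in_channels) stop("input channel mismatch")
  tape <- tape_new()
  pn <- lapply(model$params, function(p) nd_leaf(tape, p, param = train))
  x <- nd_leaf(tape, x_array)
  out <- if (cfg$arch == "resunet") forward_resunet(tape, pn, x, cfg)
         else forward_stdunet(tape, pn, x, cfg)
  list(tape = tape, out = out, pn = pn)
}

#' Run the network on a single patch
#'
#' Forward pass mapping a patch (spatial dims divisible by `2^levels`) to a
#' voxelwise tumor probability map of the same spatial shape, values strictly
#' in (0, 1).
#'
#' @param model a `petseg_model`.
#' @param x 3D array (or 4D with a channel dim).
#' @return 3D array of probabilities, same spatial dims as the input.
#' @export
net_forward <- function(model, x) {
  g <- net_graph(model, x, train = FALSE)
  v <- g$out$value
  array(v, dim(v)[1:3])
}

#' Layer-by-layer parameter summary
#'
#' @param object a `petseg_model`.
#' @param ... unused.
#' @return Invisibly, a data frame of parameter names, shapes and counts.
#' @export
summary.petseg_model <- function(object, ...) {
  df <- data.frame(
    parameter = names(object$params),
    shape = vapply(object$params, function(p)
      paste(if (is.null(dim(p))) length(p) else dim(p), collapse = "x"), ""),
    count = vapply(object$params, length, 1L),
    row.names = NULL)
  print(object)
  print(df, row.names = FALSE)
  invisible(df)
}
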