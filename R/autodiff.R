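# Minimal reverse-mode automatic differentiation over R arrays, sufficient
# for the U-Net graphs built in network.R. A tape records nodes in creation
# order (which is a topological order); backward() walks it in reverse.
# Feature maps are 4D arrays with dims (X, Y, Z, C); squeeze-and-excitation
# descriptors are plain vectors.

tape_new <- function() {
  t <- new.env(parent = emptyenv())
  t$nodes <- vector("list", 256)
  t$n <- 0L
  t
}

node_new <- function(tape, value, parents = list(), backfn = NULL) {
  nd <- new.env(parent = emptyenv())
  nd$value <- value
  nd$grad <- NULL
  nd$parents <- parents
  nd$backfn <- backfn
  nd$req <- is.null(backfn) && length(parents) == 0 && isTRUE(attr(value, "param")) ||
    any(vapply(parents, function(p) p$req, TRUE))
  if (tape$n == length(tape$nodes))
    tape$nodes <- c(tape$nodes, vector("list", length(tape$nodes)))
  tape$n <- tape$n + 1L
  tape$nodes[[tape$n]] <- nd
  nd
}

nd_leaf <- function(tape, value, param = FALSE) {
  nd <- node_new(tape, value)
  nd$req <- param
  nd
}

acc_grad <- function(nd, g) {
  if (!nd$req) return(invisible())
  nd$grad <- if (is.null(nd$grad)) g else nd$grad + g
  invisible()
}

backward <- function(tape, out, seed_grad) {
  out$grad <- seed_grad
  for (i in rev(seq_len(tape$n))) {
    nd <- tape$nodes[[i]]
    if (!is.null(nd$grad) && !is.null(nd$backfn)) nd$backfn(nd)
  }
  invisible()
}

dim4 <- function(x) {
  d <- dim(x)
  if (length(d) != 4) stop("expected a 4D (X,Y,Z,C) array")
  as.integer(d)
}

# ---- convolution ----------------------------------------------------------

nd_conv <- function(tape, x, w, b, stride = 1L, pad = NULL) {
  kd <- dim(w$value)
  if (is.null(pad)) pad <- (kd[1] - 1L) %/% 2L
  xd <- dim4(x$value)
  val <- .cpp_conv3d_fwd(x$value, xd, w$value, as.integer(kd), b$value,
                         as.integer(stride), as.integer(pad))
  node_new(tape, val, list(x = x, w = w, b = b), function(nd) {
    g <- nd$grad
    yd <- dim4(g)
    if (nd$parents$x$req)
      acc_grad(nd$parents$x,
               .cpp_conv3d_bwd_input(g, yd, nd$parents$w$value, as.integer(kd),
                                     xd, as.integer(stride), as.integer(pad)))
    if (nd$parents$w$req)
      acc_grad(nd$parents$w,
               .cpp_conv3d_bwd_weight(nd$parents$x$value, xd, g, yd,
                                      as.integer(kd), as.integer(stride),
                                      as.integer(pad)))
    if (nd$parents$b$req) {
      m <- matrix(g, ncol = yd[4])
      acc_grad(nd$parents$b, colSums(m))
    }
  })
}

# Transposed convolution with stride 2 and kernel 3, exact transpose of the
# matching strided convolution; doubles each spatial dim. Weights are stored
# in convolution orientation: dims (k,k,k, out_channels, in_channels).
nd_convT <- function(tape, x, w, b) {
  kd <- dim(w$value)
  pad <- (kd[1] - 1L) %/% 2L
  xd <- dim4(x$value)
  od <- c(2L * xd[1:3], kd[4])
  val <- .cpp_conv3d_bwd_input(x$value, xd, w$value, as.integer(kd),
                               as.integer(od), 2L, as.integer(pad))
  val <- val + rep(b$value, each = prod(od[1:3]))
  node_new(tape, val, list(x = x, w = w, b = b), function(nd) {
    g <- nd$grad
    if (nd$parents$x$req)
      acc_grad(nd$parents$x,
               .cpp_conv3d_fwd(g, as.integer(od), nd$parents$w$value,
                               as.integer(kd), numeric(kd[5]), 2L,
                               as.integer(pad)))
    if (nd$parents$w$req)
      acc_grad(nd$parents$w,
               .cpp_conv3d_bwd_weight(g, as.integer(od), nd$parents$x$value,
                                      xd, as.integer(kd), 2L, as.integer(pad)))
    if (nd$parents$b$req)
      acc_grad(nd$parents$b, colSums(matrix(g, ncol = od[4])))
  })
}

# ---- normalization and activations ----------------------------------------

nd_inorm <- function(tape, x, gamma, beta, eps = 1e-5) {
  d <- dim4(x$value)
  ns <- prod(d[1:3])
  m <- matrix(x$value, nrow = ns, ncol = d[4])
  mu <- colMeans(m)
  xc <- m - rep(mu, each = ns)
  v <- colMeans(xc * xc)
  inv <- 1 / sqrt(v + eps)
  xhat <- xc * rep(inv, each = ns)
  y <- xhat * rep(gamma$value, each = ns) + rep(beta$value, each = ns)
  nd <- node_new(tape, array(y, d), list(x = x, gamma = gamma, beta = beta),
                 function(nd) {
    g <- matrix(nd$grad, nrow = ns, ncol = d[4])
    if (nd$parents$gamma$req) acc_grad(nd$parents$gamma, colSums(g * xhat))
    if (nd$parents$beta$req) acc_grad(nd$parents$beta, colSums(g))
    if (nd$parents$x$req) {
      gg <- g * rep(nd$parents$gamma$value, each = ns)
      mg <- colMeans(gg)
      mgx <- colMeans(gg * xhat)
      dx <- (gg - rep(mg, each = ns) - xhat * rep(mgx, each = ns)) *
        rep(inv, each = ns)
      acc_grad(nd$parents$x, array(dx, d))
    }
  })
  nd
}

nd_relu <- function(tape, x) {
  mask <- x$value > 0
  node_new(tape, x$value * mask, list(x = x), function(nd) {
    if (nd$parents$x$req) acc_grad(nd$parents$x, nd$grad * mask)
  })
}

nd_sigmoid <- function(tape, x) {
  s <- 1 / (1 + exp(-x$value))
  node_new(tape, s, list(x = x), function(nd) {
    if (nd$parents$x$req) acc_grad(nd$parents$x, nd$grad * s * (1 - s))
  })
}

nd_add <- function(tape, a, b) {
  node_new(tape, a$value + b$value, list(a = a, b = b), function(nd) {
    if (nd$parents$a$req) acc_grad(nd$parents$a, nd$grad)
    if (nd$parents$b$req) acc_grad(nd$parents$b, nd$grad)
  })
}

nd_emax <- function(tape, a, b) {
  amax <- a$value >= b$value
  node_new(tape, pmax(a$value, b$value), list(a = a, b = b), function(nd) {
    if (nd$parents$a$req) acc_grad(nd$parents$a, nd$grad * amax)
    if (nd$parents$b$req) acc_grad(nd$parents$b, nd$grad * (1 - amax))
  })
}

# ---- squeeze-and-excitation primitives ------------------------------------

# global average pool: (X,Y,Z,C) -> length-C vector
nd_gap <- function(tape, x) {
  d <- dim4(x$value)
  ns <- prod(d[1:3])
  val <- colMeans(matrix(x$value, nrow = ns, ncol = d[4]))
  node_new(tape, val, list(x = x), function(nd) {
    if (nd$parents$x$req)
      acc_grad(nd$parents$x, array(rep(nd$grad / ns, each = ns), d))
  })
}

# dense layer on a vector: y = t(W) v + b, W dims (in, out)
nd_dense <- function(tape, v, w, b) {
  val <- as.numeric(crossprod(w$value, v$value)) + b$value
  node_new(tape, val, list(v = v, w = w, b = b), function(nd) {
    g <- nd$grad
    if (nd$parents$v$req) acc_grad(nd$parents$v, as.numeric(nd$parents$w$value %*% g))
    if (nd$parents$w$req) acc_grad(nd$parents$w, outer(nd$parents$v$value, g))
    if (nd$parents$b$req) acc_grad(nd$parents$b, g)
  })
}

# per-channel gate: x * g[c]
nd_cmul <- function(tape, x, gate) {
  d <- dim4(x$value)
  ns <- prod(d[1:3])
  gr <- rep(gate$value, each = ns)
  node_new(tape, array(x$value * gr, d), list(x = x, gate = gate), function(nd) {
    if (nd$parents$x$req) acc_grad(nd$parents$x, array(nd$grad * gr, d))
    if (nd$parents$gate$req)
      acc_grad(nd$parents$gate,
               colSums(matrix(nd$grad * nd$parents$x$value, nrow = ns)))
  })
}

# per-voxel gate: x * s[x,y,z,1] broadcast over channels
nd_smul <- function(tape, x, gate) {
  d <- dim4(x$value)
  ns <- prod(d[1:3])
  sv <- as.numeric(gate$value)  # length ns
  gr <- rep(sv, times = d[4])
  node_new(tape, array(x$value * gr, d), list(x = x, gate = gate), function(nd) {
    if (nd$parents$x$req) acc_grad(nd$parents$x, array(nd$grad * gr, d))
    if (nd$parents$gate$req) {
      gs <- rowSums(matrix(nd$grad * nd$parents$x$value, nrow = ns))
      acc_grad(nd$parents$gate, array(gs, c(d[1:3], 1L)))
    }
  })
}

nd_concat <- function(tape, a, b) {
  da <- dim4(a$value); db <- dim4(b$value)
  if (!identical(da[1:3], db[1:3])) stop("concat: spatial dims differ")
  val <- array(c(a$value, b$value), c(da[1:3], da[4] + db[4]))
  node_new(tape, val, list(a = a, b = b), function(nd) {
    ns <- prod(da[1:3])
    g <- nd$grad
    if (nd$parents$a$req)
      acc_grad(nd$parents$a, array(g[seq_len(ns * da[4])], da))
    if (nd$parents$b$req)
      acc_grad(nd$parents$b, array(g[ns * da[4] + seq_len(ns * db[4])], db))
  })
}

nd_maxpool <- function(tape, x) {
  d <- dim4(x$value)
  r <- .cpp_maxpool3d_fwd(x$value, d)
  node_new(tape, r$value, list(x = x), function(nd) {
    if (nd$parents$x$req)
      acc_grad(nd$parents$x, .cpp_maxpool3d_bwd(nd$grad, r$argmax, d))
  })
}

nd_upsample2x <- function(tape, x) {
  d <- dim4(x$value)
  node_new(tape, .cpp_upsample2x_fwd(x$value, d), list(x = x), function(nd) {
    if (nd$parents$x$req)
      acc_grad(nd$parents$x, .cpp_upsample2x_bwd(nd$grad, d))
  })
}
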