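# Independent oracles and small fixture builders used across the suite.
# Oracles are deliberately naive (triple loops, direct counting) and share no
# code with the implementation paths they check.

# Node-centered trilinear resampling, brute force.
oracle_resample <- function(values, spacing, target) {
  d <- dim(values)
  od <- pmax(1L, as.integer(round((d - 1) * spacing / target)) + 1L)
  out <- array(0, od)
  for (k in seq_len(od[3])) for (j in seq_len(od[2])) for (i in seq_len(od[1])) {
    u <- c((i - 1) * target[1] / spacing[1],
           (j - 1) * target[2] / spacing[2],
           (k - 1) * target[3] / spacing[3])
    u <- pmin(pmax(u, 0), d - 1)
    f <- pmin(floor(u), pmax(d - 2, 0))
    w <- u - f
    acc <- 0
    for (dz in 0:1) for (dy in 0:1) for (dx in 0:1) {
      ix <- min(f[1] + dx, d[1] - 1); iy <- min(f[2] + dy, d[2] - 1)
      iz <- min(f[3] + dz, d[3] - 1)
      wt <- (if (dx) w[1] else 1 - w[1]) * (if (dy) w[2] else 1 - w[2]) *
        (if (dz) w[3] else 1 - w[3])
      acc <- acc + wt * values[ix + 1, iy + 1, iz + 1]
    }
    out[i, j, k] <- acc
  }
  out
}

# Voxel-by-voxel confusion counts.
oracle_confusion <- function(pred, truth) {
  tp <- 0L; fp <- 0L; fn <- 0L; tn <- 0L
  for (i in seq_along(pred)) {
    if (pred[i] != 0 && truth[i] != 0) tp <- tp + 1L
    else if (pred[i] != 0) fp <- fp + 1L
    else if (truth[i] != 0) fn <- fn + 1L
    else tn <- tn + 1L
  }
  list(tp = tp, fp = fp, fn = fn, tn = tn)
}

# A minimal valid case on a given grid for patch/augmentation tests.
make_toy_case <- function(d = c(8, 8, 8), spacing = c(4, 4, 2), seed = 1) {
  set.seed(seed)
  vol <- array(abs(rnorm(prod(d))) + 0.5, d)
  msk <- array(0, d)
  ctr <- pmax(d %/% 2, 1)
  msk[ctr[1], ctr[2], ctr[3]] <- 1
  patient_case(volume3d(vol, spacing), binary_mask3d(msk, spacing),
               center = "toy", case_id = sprintf("toy_%d", seed))
}

make_toy_patch <- function(d = c(8, 8, 8), spacing = c(1, 1, 1), seed = 1) {
  set.seed(seed)
  msk <- array(0, d)
  msk[2:3, 2:3, 2:3] <- 1
  structure(list(volume = array(rnorm(prod(d)), d), mask = msk,
                 spacing = spacing, case_id = "toy", corner = c(0L, 0L, 0L)),
            class = "petseg_patch")
}

# Metadata-only case stubs (center bookkeeping tests do not need voxel data).
make_stub_cases <- function(center_sizes) {
  out <- list()
  for (ctr in names(center_sizes)) {
    for (i in seq_len(center_sizes[[ctr]])) {
      id <- sprintf("%s_%03d", ctr, i)
      out[[id]] <- list(center = ctr, case_id = id)
    }
  }
  out
}

tiny_resunet <- function(seed = 1, channels = c(4, 8), levels = 2)
  init_model(model_config("resunet", levels = levels, channels = channels),
             seed = seed)

tiny_stdunet <- function(seed = 1, channels = c(4, 8), levels = 2)
  init_model(model_config("stdunet", levels = levels, channels = channels),
             seed = seed)
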