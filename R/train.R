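# Patch-based optimization loop: Adam with cosine-annealing warm restarts,
# Soft Dice objective, per-epoch validation, best-checkpoint tracking.

#' Training configuration
#'
#' Defaults follow the full-scale recipe: 400 epochs, batch size 2, patches
#' of 128 x 128 x 64 voxels, Adam with beta1 = 0.9 and beta2 = 0.99, and a
#' cosine annealing schedule from `lr_max = 1e-4` to `lr_min = 1e-6`
#' restarting every 25 epochs, adjusted once per epoch. 20% of training
#' samples are set aside for validation. `steps_per_epoch = NULL` means one
#' patch per training case per epoch (in batches of `batch_size`).
#'
#' @param epochs training epochs.
#' @param batch_size patches per optimizer step.
#' @param patch_size integer triple of voxels; must be divisible by
#'   `2^levels` of the model it trains.
#' @param beta1,beta2 Adam exponential decay rates for moment estimates.
#' @param lr_max,lr_min cosine schedule endpoints.
#' @param cycle_epochs cosine restart period in epochs.
#' @param restarts if `FALSE`, a single cosine decay over all epochs is used
#'   instead of warm restarts.
#' @param steps_per_epoch optimizer steps per epoch, or `NULL` for
#'   `ceiling(n_train / batch_size)`.
#' @param validation_fraction fraction of training samples set aside, in
#'   (0, 1).
#' @param augment an [augment_config], or `NULL` to disable augmentation.
#' @param foreground_bias fraction of patch draws forced to contain tumor
#'   (see [extract_patch()]).
#' @param target_spacing common analysis grid the cases live on, mm.
#' @param adam_eps Adam denominator epsilon.
#' @return An object of class `train_config`.
#' @export
train_config <- function(epochs = 400, batch_size = 2,
                         patch_size = c(128, 128, 64),
                         beta1 = 0.9, beta2 = 0.99,
                         lr_max = 1e-4, lr_min = 1e-6, cycle_epochs = 25,
                         restarts = TRUE, steps_per_epoch = NULL,
                         validation_fraction = 0.2,
                         augment = augment_config(),
                         foreground_bias = 0.5,
                         target_spacing = c(4, 4, 2),
                         adam_eps = 1e-8) {
  if (lr_min >= lr_max) stop("`lr_min` must be below `lr_max`")
  if (cycle_epochs < 1) stop("`cycle_epochs` must be >= 1")
  if (validation_fraction <= 0 || validation_fraction >= 1)
    stop("`validation_fraction` must be in (0, 1)")
  structure(list(epochs = as.integer(epochs), batch_size = as.integer(batch_size),
                 patch_size = as.integer(check_len3(patch_size, "patch_size")),
                 beta1 = beta1, beta2 = beta2, lr_max = lr_max, lr_min = lr_min,
                 cycle_epochs = as.integer(cycle_epochs), restarts = restarts,
                 steps_per_epoch = steps_per_epoch,
                 validation_fraction = validation_fraction,
                 augment = augment, foreground_bias = foreground_bias,
                 target_spacing = check_len3(target_spacing, "target_spacing"),
                 adam_eps = adam_eps),
            class = "train_config")
}

#' Desk-scale training profile
#'
#' A scaled-down [train_config()] for small phantom cohorts on one CPU:
#' 16^3 patches, short schedules, small learning-rate cycle. The higher
#' learning rate compensates for the small number of optimizer steps; all
#' other conventions are unchanged.
#'
#' @param epochs,cycle_epochs,patch_size,lr_max,lr_min,steps_per_epoch,... see
#'   [train_config()].
#' @return A `train_config`.
#' @export
desk_train_config <- function(epochs = 30, cycle_epochs = 30,
                              patch_size = c(16, 16, 16),
                              lr_max = 3e-3, lr_min = 1e-4,
                              steps_per_epoch = NULL, ...) {
  train_config(epochs = epochs, cycle_epochs = cycle_epochs,
               patch_size = patch_size, lr_max = lr_max, lr_min = lr_min,
               steps_per_epoch = steps_per_epoch, ...)
}

#' Cosine-annealing learning rate with warm restarts
#'
#' `lr(t) = lr_min + (lr_max - lr_min)/2 * (1 + cos(pi * (t mod C) / C))`
#' with period `C = cycle_epochs`: `lr_max` at each cycle start, decaying to
#' `lr_min` at the cycle end, restarting every `C` epochs. With
#' `restarts = FALSE` a single decay spanning all epochs is used.
#'
#' @param epoch epoch index (0-based; fractional values allowed).
#' @param config a [train_config].
#' @return The learning rate.
#' @export
cosine_lr <- function(epoch, config = train_config()) {
  stopifnot(all(epoch >= 0))
  phase <- if (config$restarts) (epoch %% config$cycle_epochs) / config$cycle_epochs
           else pmin(epoch / config$epochs, 1)
  config$lr_min + 0.5 * (config$lr_max - config$lr_min) * (1 + cos(pi * phase))
}

#' Split cases into training and validation sets
#'
#' Random, reproducible, disjoint and exhaustive split, stratified by center
#' (each center contributes approximately `fraction` of its cases to the
#' validation set, at least one case overall).
#'
#' @param cases list of [patient_case] objects (at least 2).
#' @param fraction validation fraction.
#' @param seed integer seed.
#' @return A list with `train` and `val` lists of cases.
#' @export
split_train_val <- function(cases, fraction = 0.2, seed = 1) {
  if (length(cases) < 2) stop("need at least 2 cases to split")
  centers <- vapply(cases, function(cs) cs$center, "")
  with_seed(seed, {
    val_idx <- integer(0)
    for (ctr in unique(centers)) {
      idx <- which(centers == ctr)
      k <- round(length(idx) * fraction)
      if (k > 0) val_idx <- c(val_idx, sample(idx, k))
    }
    if (length(val_idx) == 0) val_idx <- sample(seq_along(cases), 1)
    if (length(val_idx) == length(cases)) val_idx <- val_idx[-1]
    list(train = cases[setdiff(seq_along(cases), val_idx)],
         val = cases[sort(val_idx)])
  })
}

adam_new <- function(params, cfg) {
  list(m = lapply(params, function(p) p * 0),
       v = lapply(params, function(p) p * 0),
       t = 0L)
}

adam_step <- function(params, grads, st, lr, cfg) {
  st$t <- st$t + 1L
  bc1 <- 1 - cfg$beta1^st$t
  bc2 <- 1 - cfg$beta2^st$t
  for (nm in names(params)) {
    g <- grads[[nm]]
    if (is.null(g)) next
    st$m[[nm]] <- cfg$beta1 * st$m[[nm]] + (1 - cfg$beta1) * g
    st$v[[nm]] <- cfg$beta2 * st$v[[nm]] + (1 - cfg$beta2) * g * g
    params[[nm]] <- params[[nm]] -
      lr * (st$m[[nm]] / bc1) / (sqrt(st$v[[nm]] / bc2) + cfg$adam_eps)
  }
  list(params = params, state = st)
}

# Deterministic validation patch: centered on the tumor centroid, clipped to
# the volume (zero-padded if the volume is smaller than the patch).
center_patch <- function(case, patch_size) {
  vol <- case$volume$values
  msk <- case$truth$values
  d <- dim(vol)
  pd <- pmax(d, patch_size)
  if (any(pd > d)) {
    pvol <- array(0, pd); pmsk <- array(0, pd)
    pvol[seq_len(d[1]), seq_len(d[2]), seq_len(d[3])] <- vol
    pmsk[seq_len(d[1]), seq_len(d[2]), seq_len(d[3])] <- msk
    vol <- pvol; msk <- pmsk; d <- pd
  }
  ctr <- round(colMeans(which(msk != 0, arr.ind = TRUE)))
  corner <- pmin(pmax(ctr - patch_size %/% 2, 1), d - patch_size + 1)
  sl <- lapply(1:3, function(a) corner[a] - 1 + seq_len(patch_size[a]))
  list(volume = vol[sl[[1]], sl[[2]], sl[[3]], drop = FALSE],
       mask = msk[sl[[1]], sl[[2]], sl[[3]], drop = FALSE])
}

run_batch <- function(model, batch, train = TRUE) {
  grads <- NULL
  loss <- 0
  for (b in batch) {
    g <- net_graph(model, b$volume, train = train)
    pred <- array(g$out$value, dim(b$volume))
    if (any(!is.finite(pred)))
      stop_petseg("non-finite network output", "petseg_training_error")
    loss <- loss + soft_dice_loss(pred, b$mask)
    if (train) {
      seed <- array(soft_dice_grad(pred, b$mask) / length(batch),
                    dim(g$out$value))
      backward(g$tape, g$out, seed)
      gr <- lapply(g$pn, function(nd) nd$grad)
      grads <- if (is.null(grads)) gr else
        mapply(function(a, b_) if (is.null(a)) b_ else if (is.null(b_)) a else a + b_,
               grads, gr, SIMPLIFY = FALSE)
    }
  }
  list(loss = loss / length(batch), grads = grads)
}

#' Fit a segmentation network to a set of cases
#'
#' The main model-fitting entry point. Cases must already live on the common
#' analysis grid (see [preprocess_case()]). A validation subset is split off
#' (stratified by center), and the network is trained on randomly extracted,
#' augmented patches with the Soft Dice loss, Adam updates and a
#' cosine-annealed learning rate adjusted each epoch. The checkpoint with
#' the best validation DSC (masks thresholded at 0.5) is retained alongside
#' the final parameters. Fully reproducible for a fixed `seed`.
#'
#' @param cases list of [patient_case] objects, or a `petseg_cohort`.
#' @param model a [model_config], or an already initialized `petseg_model`
#'   to continue from.
#' @param control a [train_config].
#' @param seed integer seed governing the split, initialization, patch
#'   draws and augmentation.
#' @param verbose print a line per epoch.
#' @return An object of class `petseg_fit` with elements `model` (final
#'   parameters), `best_model`, `history` (one row per epoch: training loss,
#'   validation loss, validation DSC, learning rate), `control`, case-id
#'   bookkeeping and the seed.
#' @export
petseg_fit <- function(cases, model = model_config(), control = train_config(),
                       seed = 1, verbose = FALSE) {
  if (inherits(cases, "petseg_cohort")) cases <- cases$cases
  stopifnot(inherits(control, "train_config"))
  if (inherits(model, "model_config")) model <- init_model(model, seed = seed)
  stopifnot(inherits(model, "petseg_model"))
  check_input_dims(c(control$patch_size, 1L), model$config)

  sp <- split_train_val(cases, control$validation_fraction, seed = seed)
  tr <- sp$train; va <- sp$val
  steps <- control$steps_per_epoch %||%
    max(1L, as.integer(ceiling(length(tr) / control$batch_size)))

  history <- data.frame(epoch = integer(0), lr = numeric(0),
                        train_loss = numeric(0), val_loss = numeric(0),
                        val_dsc = numeric(0))
  best <- list(dsc = -Inf, params = model$params)
  st <- adam_new(model$params, control)

  with_seed(seed + 1L, {
    for (ep in seq_len(control$epochs)) {
      lr <- cosine_lr(ep - 1, control)
      ep_loss <- 0
      for (s in seq_len(steps)) {
        ids <- sample.int(length(tr), control$batch_size, replace = length(tr) < control$batch_size)
        batch <- lapply(tr[ids], function(cs) {
          p <- extract_patch(cs, control$patch_size, control$foreground_bias)
          if (!is.null(control$augment)) p <- augment(p, control$augment)
          p
        })
        rb <- run_batch(model, batch, train = TRUE)
        if (!is.finite(rb$loss))
          stop_petseg(sprintf("non-finite loss at epoch %d step %d (lr %.2g)",
                              ep, s, lr), "petseg_training_error")
        upd <- adam_step(model$params, rb$grads, st, lr, control)
        model$params <- upd$params
        st <- upd$state
        ep_loss <- ep_loss + rb$loss
      }
      # validation on deterministic tumor-centered patches
      val_loss <- NA_real_; val_dsc <- NA_real_
      if (length(va) > 0) {
        vl <- 0; vd <- 0
        for (cs in va) {
          cp <- center_patch(cs, control$patch_size)
          pred <- net_forward(model, cp$volume)
          vl <- vl + soft_dice_loss(pred, cp$mask)
          vd <- vd + case_metrics((pred >= 0.5) + 0, cp$mask)$dsc
        }
        val_loss <- vl / length(va); val_dsc <- vd / length(va)
        if (val_dsc > best$dsc) best <- list(dsc = val_dsc, params = model$params)
      }
      history <- rbind(history, data.frame(
        epoch = ep, lr = lr, train_loss = ep_loss / steps,
        val_loss = val_loss, val_dsc = val_dsc))
      if (verbose)
        message(sprintf("epoch %3d  lr %.2e  loss %.4f  val_loss %s  val_dsc %s",
                        ep, lr, ep_loss / steps,
                        formatC(val_loss, format = "f", digits = 4),
                        formatC(val_dsc, format = "f", digits = 4)))
    }
  })

  structure(list(
    model = model,
    best_model = structure(list(config = model$config, params = best$params,
                                n_params = model$n_params),
                           class = "petseg_model"),
    best_val_dsc = if (is.finite(best$dsc)) best$dsc else NA_real_,
    history = history, control = control, seed = seed,
    train_ids = vapply(tr, function(cs) cs$case_id, ""),
    val_ids = vapply(va, function(cs) cs$case_id, "")),
    class = "petseg_fit")
}

#' @export
print.petseg_fit <- function(x, ...) {
  cat(sprintf("<petseg_fit> %s, %d epochs, %d train / %d val cases\n",
              x$model$config$arch, nrow(x$history),
              length(x$train_ids), length(x$val_ids)))
  if (nrow(x$history) > 0)
    cat(sprintf("  final train loss %.4f; best val DSC %.3f\n",
                tail(x$history$train_loss, 1), x$best_val_dsc))
  invisible(x)
}

#' @export
summary.petseg_fit <- function(object, ...) {
  print(object)
  cat("\nModel:\n"); print(object$model)
  if (nrow(object$history) > 0) {
    cat("\nLast epochs:\n")
    print(tail(object$history, 5), row.names = FALSE)
  }
  invisible(object)
}

#' @export
coef.petseg_fit <- function(object, best = FALSE, ...) {
  if (best) object$best_model$params else object$model$params
}

#' Plot training history
#'
#' Training and validation Soft Dice loss per epoch, with validation DSC on
#' a second panel.
#'
#' @param x a `petseg_fit`.
#' @param ... passed to [graphics::matplot()].
#' @export
plot.petseg_fit <- function(x, ...) {
  h <- x$history
  if (nrow(h) == 0) { warning("empty history"); return(invisible(x)) }
  op <- graphics::par(mfrow = c(1, 2), mar = c(4, 4, 2, 1))
  on.exit(graphics::par(op))
  graphics::matplot(h$epoch, cbind(h$train_loss, h$val_loss), type = "l",
                    lty = 1, col = c("black", "red3"),
                    xlab = "epoch", ylab = "Soft Dice loss", ...)
  graphics::legend("topright", c("train", "validation"), lty = 1,
                   col = c("black", "red3"), bty = "n")
  graphics::plot(h$epoch, h$val_dsc, type = "l", col = "blue3",
                 xlab = "epoch", ylab = "validation DSC")
  invisible(x)
}
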