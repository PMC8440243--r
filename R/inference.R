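# Whole-volume prediction: sliding windows of the training patch size with
# 50% overlap, averaged probabilities, inverse resampling to the native grid.

#' Predict a probability map for a whole volume
#'
#' Runs the network over sliding windows of `window` voxels with the given
#' overlap, averaging probabilities where windows overlap (the internal
#' weight map is asserted to be positive everywhere, so averaged weights sum
#' to one). Volumes smaller than one window are zero-padded and the output
#' cropped back, so the output shape always equals the input shape. On a
#' volume of exactly one window this reduces to a single forward pass.
#'
#' @param fit a `petseg_fit` (or a bare `petseg_model`).
#' @param v a [volume3d] preprocessed to the analysis grid (resampled and
#'   Z-score normalized), or a [patient_case] whose volume is.
#' @param window integer triple; defaults to the training patch size.
#' @param overlap fractional window overlap in (0, 1\]; 0.5 by default.
#' @param use_best use the best-validation checkpoint rather than the final
#'   parameters (fits only).
#' @return A [volume3d] whose values are tumor probabilities in (0, 1).
#' @export
predict_volume <- function(fit, v, window = NULL, overlap = 0.5,
                           use_best = TRUE) {
  model <- if (inherits(fit, "petseg_fit")) {
    if (use_best) fit$best_model else fit$model
  } else fit
  if (!inherits(model, "petseg_model"))
    stop_petseg("not a trained model or fit", "petseg_checkpoint_error")
  if (inherits(v, "patient_case")) v <- v$volume
  stopifnot(inherits(v, "volume3d"))
  if (is.null(window))
    window <- if (inherits(fit, "petseg_fit")) fit$control$patch_size
              else stop("`window` must be given for a bare model")
  window <- as.integer(check_len3(window, "window"))
  check_input_dims(c(window, 1L), model$config)

  d0 <- dim(v$values)
  d <- pmax(d0, window)
  vol <- array(0, d)
  vol[seq_len(d0[1]), seq_len(d0[2]), seq_len(d0[3])] <- v$values

  starts <- function(n, w) {
    if (n == w) return(0L)
    s <- as.integer(seq(0L, n - w, by = max(1L, as.integer(round(w * (1 - overlap))))))
    sort(unique(c(s, n - w)))
  }
  sx <- starts(d[1], window[1]); sy <- starts(d[2], window[2])
  sz <- starts(d[3], window[3])

  acc <- array(0, d); wgt <- array(0, d)
  for (z0 in sz) for (y0 in sy) for (x0 in sx) {
    sl <- list(x0 + seq_len(window[1]), y0 + seq_len(window[2]),
               z0 + seq_len(window[3]))
    p <- net_forward(model, vol[sl[[1]], sl[[2]], sl[[3]], drop = FALSE])
    acc[sl[[1]], sl[[2]], sl[[3]]] <- acc[sl[[1]], sl[[2]], sl[[3]]] + p
    wgt[sl[[1]], sl[[2]], sl[[3]]] <- wgt[sl[[1]], sl[[2]], sl[[3]]] + 1
  }
  stopifnot(all(wgt > 0))
  prob <- acc / wgt
  volume3d(prob[seq_len(d0[1]), seq_len(d0[2]), seq_len(d0[3]), drop = FALSE],
           v$spacing, v$origin)
}

#' Threshold a probability map into a binary mask
#'
#' `mask = p >= threshold`; monotone in the threshold. An optional
#' largest-connected-component cleanup is available but OFF by default (the
#' pipeline uses no anatomical post-processing).
#'
#' @param p a [volume3d] of probabilities (or plain array with spacing
#'   attribute semantics via `spacing`).
#' @param threshold in (0, 1).
#' @param largest_component keep only the largest 6-connected component.
#' @param spacing spacing when `p` is a plain array.
#' @return A [binary_mask3d].
#' @export
binarize <- function(p, threshold = 0.5, largest_component = FALSE,
                     spacing = NULL) {
  if (inherits(p, "volume3d")) { spacing <- p$spacing; p <- p$values }
  if (is.null(spacing)) stop("`spacing` required for plain arrays")
  if (threshold <= 0 || threshold >= 1) stop("`threshold` must be in (0, 1)")
  m <- (p >= threshold) + 0
  if (largest_component && sum(m) > 0) m <- largest_cc(m)
  binary_mask3d(array(m, dim(p)), spacing)
}

# Largest 6-connected foreground component (BFS flood fill).
largest_cc <- function(m) {
  d <- dim(m)
  lab <- array(0L, d)
  cur <- 0L
  nbr <- rbind(c(1, 0, 0), c(-1, 0, 0), c(0, 1, 0), c(0, -1, 0),
               c(0, 0, 1), c(0, 0, -1))
  sizes <- integer(0)
  fg <- which(m != 0)
  for (start in fg) {
    if (lab[start] != 0L) next
    cur <- cur + 1L
    queue <- start
    lab[start] <- cur
    n <- 0L
    while (length(queue) > 0) {
      i <- queue[[1]]; queue <- queue[-1]
      n <- n + 1L
      co <- arrayInd(i, d)
      for (k in 1:6) {
        cc <- co + nbr[k, ]
        if (any(cc < 1) || any(cc > d)) next
        j <- cc[1] + d[1] * (cc[2] - 1 + d[2] * (cc[3] - 1))
        if (m[j] != 0 && lab[j] == 0L) { lab[j] <- cur; queue <- c(queue, j) }
      }
    }
    sizes[cur] <- n
  }
  (lab == which.max(sizes)) + 0
}

#' Resample a predicted mask back to a native grid
#'
#' Inverse of the preprocessing resampling: linear interpolation of the
#' {0,1} field followed by a 0.5 threshold. When the native spacing equals
#' the mask's spacing this is the identity.
#'
#' @param mask a [binary_mask3d] on the analysis grid.
#' @param native_spacing numeric triple, mm.
#' @return A [binary_mask3d] on the native grid.
#' @export
to_native_grid <- function(mask, native_spacing) {
  resample_mask(mask, native_spacing)
}

#' Predict tumor masks or probability maps from a fitted model
#'
#' @param object a `petseg_fit`.
#' @param newdata a [patient_case] or [volume3d] on the analysis grid, or a
#'   list of cases / a `petseg_cohort`.
#' @param type `"mask"` (default) or `"prob"`.
#' @param threshold binarization threshold for `type = "mask"`.
#' @param use_best use the best-validation checkpoint.
#' @param ... unused.
#' @return A [binary_mask3d] or [volume3d] (or a list thereof for list
#'   input).
#' @export
predict.petseg_fit <- function(object, newdata, type = c("mask", "prob"),
                               threshold = 0.5, use_best = TRUE, ...) {
  type <- match.arg(type)
  if (inherits(newdata, "petseg_cohort")) newdata <- newdata$cases
  one <- function(v) {
    p <- predict_volume(object, v, use_best = use_best)
    if (type == "prob") p else binarize(p, threshold)
  }
  if (inherits(newdata, "patient_case") || inherits(newdata, "volume3d"))
    return(one(newdata))
  lapply(newdata, one)
}
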