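# Leave-one-center-out cross-validation, baselines, stratified analyses and
# reporting.

#' Leave-one-center-out folds
#'
#' One fold per center: the fold's test set is exactly that center's cases
#' and its training pool is all other centers (from which a validation
#' subset is later split by [split_train_val()]).
#'
#' @param cohort a `petseg_cohort` or list of [patient_case] objects from at
#'   least two centers.
#' @return A list of folds, each with `test_center`, `test_ids` and
#'   `train_ids`.
#' @export
make_folds <- function(cohort) {
  cases <- if (inherits(cohort, "petseg_cohort")) cohort$cases else cohort
  centers <- vapply(cases, function(cs) cs$center, "")
  ids <- vapply(cases, function(cs) cs$case_id, "")
  uc <- unique(centers)
  if (length(uc) < 2)
    stop("leave-one-center-out needs at least 2 centers")
  lapply(uc, function(ctr)
    list(test_center = ctr,
         test_ids = ids[centers == ctr],
         train_ids = ids[centers != ctr]))
}

eval_case_mask <- function(pred_mask, case) {
  cm <- case_metrics(pred_mask, case$truth)
  overlap <- if (is.null(case$bladder)) NA_real_ else
    sum(pred_mask$values * case$bladder$values)
  raw <- case$meta$raw_volume %||% case$volume
  data.frame(case_id = case$case_id, center = case$center,
             dsc = cm$dsc, precision = cm$precision, recall = cm$recall,
             tp = cm$tp, fp = cm$fp, fn = cm$fn,
             truth_voxels = cm$truth_voxels,
             truth_volume_cm3 = mask_volume_cm3(case$truth),
             contrast = operational_contrast(raw, case$truth, case$bladder),
             bladder_overlap = overlap, stringsAsFactors = FALSE)
}

#' Run multi-center cross-validation
#'
#' For every leave-one-center-out fold, trains each configured network from
#' scratch on the training centers (identical seeds and training schedule
#' across methods, so only the architecture differs), predicts the held-out
#' center, and additionally evaluates the fully automatic T40 baseline
#' (threshold at 40% of the maximum uptake within the tumor) on the same
#' test cases. All methods are evaluated on identical case lists.
#'
#' @param cohort a `petseg_cohort`, already preprocessed to the analysis
#'   grid (see [preprocess_cohort()]).
#' @param models named list of [model_config]s, e.g.
#'   `list(proposed = model_config("resunet"), stdunet = model_config("stdunet"))`.
#' @param control a [train_config].
#' @param seed integer seed.
#' @param t40_mode how the T40 baseline is regionalized: `"volume"`
#'   (default) thresholds the entire volume at 40% of the maximum uptake
#'   within the tumor, the fully automatic reading with no volume of
#'   interest, under which nearby bright structures such as the bladder are
#'   swept in; `"bbox"` restricts the search to the truth bounding box
#'   dilated by `t40_dilate` voxels (a more charitable, semi-localized
#'   emulation).
#' @param t40_dilate truth-bounding-box dilation (voxels) for
#'   `t40_mode = "bbox"`.
#' @param verbose print progress.
#' @return An object of class `petseg_cv`: `cases` (per-case metrics data
#'   frame with columns method, fold, dsc, precision, recall, ...), `folds`
#'   (per-fold per-method means), and `fits` (the trained fits, named
#'   `<method>.<center>`).
#' @export
run_cv <- function(cohort, models = list(proposed = model_config("resunet"),
                                         stdunet = model_config("stdunet")),
                   control = train_config(), seed = 1,
                   t40_mode = c("volume", "bbox"), t40_dilate = 2,
                   verbose = FALSE) {
  t40_mode <- match.arg(t40_mode)
  stopifnot(inherits(cohort, "petseg_cohort"))
  cases <- cohort$cases
  folds <- make_folds(cohort)
  rows <- list()
  fits <- list()
  for (fd in folds) {
    train_cases <- cases[fd$train_ids]
    test_cases <- cases[fd$test_ids]
    for (mname in names(models)) {
      if (verbose) message(sprintf("fold %s: training %s ...", fd$test_center, mname))
      fit <- petseg_fit(train_cases, model = models[[mname]], control = control,
                        seed = seed, verbose = FALSE)
      fits[[paste(mname, fd$test_center, sep = ".")]] <- fit
      for (cs in test_cases) {
        pm <- predict(fit, cs)
        r <- eval_case_mask(pm, cs)
        r$method <- mname; r$fold <- fd$test_center
        rows[[length(rows) + 1L]] <- r
      }
    }
    for (cs in test_cases) {
      raw <- cs$meta$raw_volume %||% cs$volume
      pm <- if (t40_mode == "bbox")
        t40_segment(raw, t40_region(cs$truth, t40_dilate))
      else
        t40_segment(raw, binary_mask3d(array(1, dim(raw$values)), raw$spacing),
                    threshold_region = cs$truth)
      r <- eval_case_mask(pm, cs)
      r$method <- "t40"; r$fold <- fd$test_center
      rows[[length(rows) + 1L]] <- r
    }
  }
  df <- do.call(rbind, rows)
  structure(list(cases = df, folds = cv_fold_table(df), fits = fits),
            class = "petseg_cv")
}

cv_fold_table <- function(df) {
  agg <- function(metric) {
    m <- stats::aggregate(df[[metric]], by = list(method = df$method, fold = df$fold), mean)
    s <- stats::aggregate(df[[metric]], by = list(method = df$method, fold = df$fold), sd)
    data.frame(method = m$method, fold = m$fold, metric = metric,
               mean = m$x, sd = s$x, stringsAsFactors = FALSE)
  }
  do.call(rbind, lapply(c("dsc", "precision", "recall"), agg))
}

#' Cross-validation summary table
#'
#' Per-fold mean +/- SD for each method and metric, plus the cross-fold
#' "Average" column computed as the unweighted arithmetic mean of the fold
#' means (with its SD across folds).
#'
#' @param cv a `petseg_cv`.
#' @return A data frame with one row per (metric, method): fold columns with
#'   "mean +/- sd" strings and an `Average` column.
#' @export
cv_table <- function(cv) {
  ft <- cv$folds
  folds <- unique(ft$fold)
  out <- list()
  for (metric in unique(ft$metric)) for (m in unique(ft$method)) {
    sub <- ft[ft$metric == metric & ft$method == m, ]
    row <- data.frame(metric = metric, method = m, stringsAsFactors = FALSE)
    for (fd in folds)
      row[[fd]] <- sprintf("%.2f ± %.2f", sub$mean[sub$fold == fd],
                           sub$sd[sub$fold == fd])
    row$Average <- sprintf("%.2f ± %.2f", mean(sub$mean), sd(sub$mean))
    out[[length(out) + 1L]] <- row
  }
  do.call(rbind, out)
}

#' Cross-fold average of fold means
#'
#' @param cv a `petseg_cv`.
#' @param metric one of `"dsc"`, `"precision"`, `"recall"`.
#' @return Named numeric vector of per-method cross-fold averages.
#' @export
cv_average <- function(cv, metric = "dsc") {
  sub <- cv$folds[cv$folds$metric == metric, ]
  vapply(split(sub$mean, sub$method), mean, 1.0)
}

#' @export
print.petseg_cv <- function(x, ...) {
  cat(sprintf("<petseg_cv> %d folds, methods: %s\n",
              length(unique(x$cases$fold)),
              paste(unique(x$cases$method), collapse = ", ")))
  print(cv_table(x), row.names = FALSE)
  invisible(x)
}

#' Stratify case metrics into volume or contrast decile groups
#'
#' Rank-based grouping (ties broken by case id) into `n_groups` groups of
#' near-equal size, with per-group mean metrics and group boundaries. If
#' there are fewer cases than groups, the group count is reduced with a
#' warning.
#'
#' @param metrics per-case metrics data frame (as in `petseg_cv$cases`,
#'   optionally restricted to one method).
#' @param by `"volume"` (uses `truth_volume_cm3`) or `"contrast"`.
#' @param n_groups number of groups (10 for deciles).
#' @return A data frame of class `stratified_report`: group index, size,
#'   value boundaries, mean dsc/precision/recall.
#' @export
stratify <- function(metrics, by = c("volume", "contrast"), n_groups = 10) {
  by <- match.arg(by)
  col <- if (by == "volume") "truth_volume_cm3" else "contrast"
  df <- metrics[!is.na(metrics[[col]]), ]
  n <- nrow(df)
  if (n < 1) stop("no cases to stratify")
  if (n < n_groups) {
    warning(sprintf("only %d cases; reducing groups from %d to %d",
                    n, n_groups, n))
    n_groups <- n
  }
  ord <- order(df[[col]], df$case_id)
  df <- df[ord, ]
  grp <- ceiling(seq_len(n) / n * n_groups)
  out <- do.call(rbind, lapply(seq_len(n_groups), function(g) {
    sub <- df[grp == g, ]
    data.frame(group = g, n = nrow(sub),
               lo = min(sub[[col]]), hi = max(sub[[col]]),
               dsc = mean(sub$dsc), precision = mean(sub$precision),
               recall = mean(sub$recall))
  }))
  attr(out, "by") <- by
  class(out) <- c("stratified_report", "data.frame")
  out
}

#' Flag outlier cases by the per-fold boxplot rule
#'
#' A case is an outlier in its fold when its DSC falls below
#' `Q1 - 1.5 * IQR` of that fold's DSC distribution.
#'
#' @param metrics per-case metrics data frame with `fold` and `dsc` columns
#'   (at least 5 cases).
#' @return The subset of outlier rows, with the applied rule recorded in the
#'   `"rule"` attribute.
#' @export
flag_outliers <- function(metrics) {
  if (nrow(metrics) < 5) stop("need at least 5 cases")
  out <- do.call(rbind, lapply(split(metrics, metrics$fold), function(sub) {
    q <- quantile(sub$dsc, c(0.25, 0.75), names = FALSE, type = 7)
    sub[sub$dsc < q[1] - 1.5 * (q[2] - q[1]), ]
  }))
  rownames(out) <- NULL
  attr(out, "rule") <- "DSC < Q1 - 1.5 IQR within fold"
  out
}

#' Paired statistical comparison of two methods
#'
#' Paired Wilcoxon signed-rank and two-sample Kolmogorov-Smirnov tests per
#' metric (and per fold when `per_fold`), on identically ordered case lists.
#' Identical paired samples are reported as no difference (p = 1).
#'
#' @param a,b per-case metrics data frames for the two methods, matched by
#'   `case_id`.
#' @param metrics metric columns to compare.
#' @param alpha significance level for the decision column.
#' @param per_fold also test within each fold.
#' @return A data frame: fold ("all" for pooled), metric, test, p.value,
#'   significant.
#' @export
compare_methods <- function(a, b, metrics = c("dsc", "precision", "recall"),
                            alpha = 0.05, per_fold = TRUE) {
  if (nrow(a) != nrow(b)) stop("case lists are not paired")
  b <- b[match(a$case_id, b$case_id), ]
  if (any(is.na(b$case_id)) || !all(a$case_id == b$case_id))
    stop("case lists are not paired")
  one <- function(x, y, fold, metric) {
    wp <- if (all(x == y)) 1 else
      suppressWarnings(wilcox.test(x, y, paired = TRUE, exact = FALSE)$p.value)
    kp <- if (all(x == y)) 1 else suppressWarnings(ks.test(x, y)$p.value)
    data.frame(fold = fold, metric = metric,
               test = c("wilcoxon", "ks"), p.value = c(wp, kp),
               significant = c(wp, kp) < alpha, stringsAsFactors = FALSE)
  }
  out <- list()
  for (metric in metrics) {
    out[[length(out) + 1L]] <- one(a[[metric]], b[[metric]], "all", metric)
    if (per_fold && !is.null(a$fold))
      for (fd in unique(a$fold)) {
        i <- a$fold == fd
        out[[length(out) + 1L]] <- one(a[[metric]][i], b[[metric]][i], fd, metric)
      }
  }
  do.call(rbind, out)
}
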