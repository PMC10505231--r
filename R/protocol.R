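## The repeated-split evaluation protocol: stratified random 60/20/20
## train/validation/test splits, repeated n_splits times with independent
## seeds; per split the two arm estimators are trained (validation used for
## snapshot selection/early stopping), the logistic fusion is fitted on the
## training-split predictions, and all metrics are measured on the test
## split with bootstrap confidence intervals.

#' Draw one stratified 60/20/20 split
#'
#' @param labels Cohort label tibble (needs `slide_id`, `tumor_type`).
#' @param train_frac,val_frac Fractions per class (test gets the rest).
#' @param seed Integer seed.
#' @return List of `slide_id` vectors `train`, `val`, `test`.
#' @export
split_cohort <- function(labels, train_frac = 0.6, val_frac = 0.2, seed = 1L) {
  stopifnot(train_frac > 0, val_frac >= 0, train_frac + val_frac < 1)
  parts <- withr::with_seed(seed, {
    purrr::map(split(labels$slide_id, labels$tumor_type), function(ids) {
      ids <- ids[sample.int(length(ids))]
      n <- length(ids)
      n_tr <- max(1L, round(train_frac * n))
      n_va <- max(1L, round(val_frac * n))
      if (n_tr + n_va >= n) abort("cohort too small for a 60/20/20 split")
      list(train = ids[seq_len(n_tr)],
           val = ids[n_tr + seq_len(n_va)],
           test = ids[(n_tr + n_va + 1):n])
    })
  })
  list(train = unlist(purrr::map(parts, "train"), use.names = FALSE),
       val = unlist(purrr::map(parts, "val"), use.names = FALSE),
       test = unlist(purrr::map(parts, "test"), use.names = FALSE))
}

#' Run the repeated-split evaluation protocol on a cohort
#'
#' `n_splits` independent stratified 60/20/20 splits (Monte-Carlo
#' cross-validation; disjoint folds cannot each hold 20% validation and 20%
#' test, so repetition replaces partitioning). Per split: both arm
#' estimators are trained, the fusion is fitted on the training-split
#' predictions and applied to the test split; FC R-squared per arm, AUCs
#' (arm AUCs use `1 - fc_hat` so oligodendroglioma is the positive class),
#' the Youden-J cutoff with its confusion metrics, a percentile bootstrap
#' CI of the fused AUC, and — when the cohort carries planted ground truth —
#' the patch-localization AUC per arm are recorded. The last row of
#' `tidy()` output is the across-split average.
#'
#' @param cohort A [simulate_cohort()] result, or a list with `bags` and
#'   `labels` (labels need `slide_id`, `fc_1p`, `fc_19q`, `tumor_type`).
#' @param n_splits Number of repeated splits (default 10).
#' @param config A [train_config()] shared by both arms.
#' @param n_boot Bootstrap replicates per split (default 1000).
#' @param ci_level Confidence level (default 0.95).
#' @param seed Master seed; all split, training and bootstrap seeds derive
#'   from it.
#' @return An object of class `eval_report`: per-split metrics (`splits`),
#'   the averaged row (`summary`), fused ROC points per split (`roc`), and
#'   the per-split fusion fits.
#' @export
run_protocol <- function(cohort, n_splits = 10L, config = train_config(),
                         n_boot = 1000L, ci_level = 0.95, seed = 1L) {
  bags <- cohort$bags
  labels <- cohort$labels
  if (nrow(labels) < 10L) abort("cohort must have at least 10 slides")
  if (length(unique(labels$tumor_type)) < 2L) {
    abort("both tumor types must be present")
  }
  labels <- dplyr::mutate(labels,
                          dplyr::across(c("fc_1p", "fc_19q"), ~ pmin(.x, 0.999)))
  has_truth <- all(c("tumor_patches", "deleted_1p", "deleted_19q") %in% names(labels))
  rows <- vector("list", n_splits)
  rocs <- vector("list", n_splits)
  fusions <- vector("list", n_splits)
  for (k in seq_len(n_splits)) {
    split_seed <- derive_seed(seed, 1000L + k)
    sp <- split_cohort(labels, seed = split_seed)
    lab <- function(ids) labels[match(ids, labels$slide_id), ]
    cfg <- config
    cfg$seed <- derive_seed(seed, 2000L + k)
    fit1 <- train_fc_estimator(bags[sp$train], lab(sp$train), "1p",
                               bags[sp$val], lab(sp$val), cfg)
    fit19 <- train_fc_estimator(bags[sp$train], lab(sp$train), "19q",
                                bags[sp$val], lab(sp$val), cfg)
    fusion <- train_logistic(
      dplyr::rename(predict_cohort(bags[sp$train], fit1, fit19),
                    fc_1p = "fc_1p_hat", fc_19q = "fc_19q_hat") |>
        dplyr::mutate(tumor_type = lab(sp$train)$tumor_type)
    )
    test_pred <- fuse_predictions(predict_cohort(bags[sp$test], fit1, fit19), fusion)
    test_lab <- lab(sp$test)
    cut <- best_cutoff(test_lab$tumor_type, test_pred$prob_oligo)
    calls <- classify(test_pred$prob_oligo, cut)
    cm <- confusion_metrics(test_lab$tumor_type, calls)
    ci <- bootstrap_ci(test_lab$tumor_type, test_pred$prob_oligo,
                       n_boot = n_boot, level = ci_level,
                       seed = derive_seed(seed, 3000L + k))
    row <- tibble::tibble(
      split = k, seed = split_seed,
      r2_1p = r_squared(test_lab$fc_1p, test_pred$fc_1p_hat),
      r2_19q = r_squared(test_lab$fc_19q, test_pred$fc_19q_hat),
      auc_1p = roc_auc(test_lab$tumor_type, 1 - test_pred$fc_1p_hat),
      auc_19q = roc_auc(test_lab$tumor_type, 1 - test_pred$fc_19q_hat),
      auc_fused = roc_auc(test_lab$tumor_type, test_pred$prob_oligo),
      ci_low = ci[["low"]], ci_high = ci[["high"]],
      best_cutoff = cut,
      coef_1p = fusion$coef_1p, coef_19q = fusion$coef_19q
    )
    row <- dplyr::bind_cols(row, cm)
    if (has_truth) {
      test_truth <- lab(sp$test)
      row$loc_auc_1p <- localization_auc(bags[sp$test], test_truth, fit1, "1p")
      row$loc_auc_19q <- localization_auc(bags[sp$test], test_truth, fit19, "19q")
    }
    rows[[k]] <- row
    rocs[[k]] <- dplyr::mutate(
      roc_points(test_lab$tumor_type, test_pred$prob_oligo), split = k,
      .before = 1)
    fusions[[k]] <- fusion
  }
  splits <- purrr::list_rbind(rows)
  metric_cols <- setdiff(names(splits), c("split", "seed"))
  summary <- dplyr::summarise(splits,
                              dplyr::across(dplyr::all_of(metric_cols), mean))
  structure(list(splits = splits, summary = summary,
                 roc = purrr::list_rbind(rocs), fusions = fusions,
                 n_splits = n_splits, n_bootstrap = as.integer(n_boot),
                 ci_level = ci_level, seed = seed, config = config),
            class = "eval_report")
}

#' @export
print.eval_report <- function(x, ...) {
  cat(sprintf("<eval_report> %d splits, %d bootstraps, %.0f%% CI\n",
              x$n_splits, x$n_bootstrap, 100 * x$ci_level))
  cat(sprintf("  mean R2: 1p %.3f, 19q %.3f | AUC: 1p %.3f, 19q %.3f, fused %.3f (CI %.3f-%.3f)\n",
              x$summary$r2_1p, x$summary$r2_19q, x$summary$auc_1p,
              x$summary$auc_19q, x$summary$auc_fused,
              x$summary$ci_low, x$summary$ci_high))
  cat(sprintf("  accuracy %.3f, precision %.3f, recall %.3f, F1 %.3f at mean cutoff %.3f\n",
              x$summary$accuracy, x$summary$precision, x$summary$recall,
              x$summary$f1, x$summary$best_cutoff))
  invisible(x)
}

#' @rdname run_protocol
#' @param x An `eval_report`.
#' @param ... Unused.
#' @exportS3Method generics::tidy
tidy.eval_report <- function(x, ...) {
  avg <- dplyr::mutate(x$summary, split = NA_integer_, seed = NA_integer_)
  dplyr::bind_rows(x$splits, avg)
}

#' @rdname run_protocol
#' @exportS3Method generics::glance
glance.eval_report <- function(x, ...) {
  dplyr::bind_cols(
    tibble::tibble(n_splits = x$n_splits, n_bootstrap = x$n_bootstrap,
                   ci_level = x$ci_level),
    x$summary
  )
}

#' @exportS3Method ggplot2::autoplot
autoplot.eval_report <- function(object, ...) {
  ggplot2::ggplot(object$roc,
                  ggplot2::aes(x = .data$fpr, y = .data$tpr,
                               group = .data$split, color = factor(.data$split))) +
    ggplot2::geom_step() +
    ggplot2::geom_abline(slope = 1, intercept = 0, linetype = "dashed") +
    ggplot2::coord_equal() +
    ggplot2::labs(x = "False positive rate", y = "True positive rate",
                  color = "Split",
                  title = "Fused oligodendroglioma ROC per test split")
}
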