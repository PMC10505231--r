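## Evaluation primitives: R-squared for the FC regressions, Mann-Whitney
## ROC AUC for the tumor-type calls, percentile bootstrap confidence
## intervals, Youden-J cutoff selection and confusion-matrix metrics.

## normalize labels to logical (positive = oligodendroglioma)
as_binary_labels <- function(labels) {
  if (is.character(labels) || is.factor(labels)) {
    as.character(labels) == "oligodendroglioma"
  } else if (is.logical(labels)) {
    labels
  } else {
    labels != 0
  }
}

#' Coefficient of determination
#'
#' `1 - SS_res / SS_tot` with the total sum of squares taken about the mean
#' of `truth`. Can be negative for predictions worse than the mean; at most 1.
#'
#' @param truth,predictions Numeric vectors of equal length >= 2.
#' @return R-squared (<= 1).
#' @export
r_squared <- function(truth, predictions) {
  if (length(truth) != length(predictions) || length(truth) < 2L) {
    abort("`truth` and `predictions` must have equal length >= 2")
  }
  ss_tot <- sum((truth - mean(truth))^2)
  if (ss_tot == 0) abort("R-squared undefined: `truth` is constant")
  1 - sum((truth - predictions)^2) / ss_tot
}

#' ROC area under the curve
#'
#' Mann-Whitney formulation: the probability that a random positive
#' outranks a random negative, with ties counted half.
#'
#' @param labels Binary labels (logical, 0/1, or
#'   `"oligodendroglioma"`/`"astrocytoma"` strings; oligodendroglioma is
#'   the positive class).
#' @param scores Numeric scores, higher = more positive.
#' @return AUC in \[0, 1\].
#' @export
roc_auc <- function(labels, scores) {
  y <- as_binary_labels(labels)
  if (length(y) != length(scores)) abort("`labels` and `scores` must align")
  n_pos <- sum(y); n_neg <- sum(!y)
  if (n_pos == 0L || n_neg == 0L) abort("both classes must be present")
  r <- rank(scores) # average ranks: ties count half
  (sum(r[y]) - n_pos * (n_pos + 1) / 2) / (n_pos * n_neg)
}

#' ROC curve points
#'
#' Sensitivity/specificity swept over all observed score cutoffs (calls are
#' positive at `score >= cutoff`).
#'
#' @inheritParams roc_auc
#' @return Tibble with `cutoff`, `tpr`, `fpr`.
#' @export
roc_points <- function(labels, scores) {
  y <- as_binary_labels(labels)
  cuts <- c(Inf, sort(unique(scores), decreasing = TRUE))
  purrr::list_rbind(purrr::map(cuts, function(ct) {
    call_pos <- scores >= ct
    tibble::tibble(cutoff = ct,
                   tpr = sum(call_pos & y) / sum(y),
                   fpr = sum(call_pos & !y) / sum(!y))
  }))
}

#' Percentile bootstrap confidence interval for a metric
#'
#' Resamples (labels, scores) pairs with replacement, stratified by class
#' so no resample loses a class, and returns the percentile interval of the
#' metric over `n_boot` replicates. Deterministic in `seed`.
#'
#' @inheritParams roc_auc
#' @param metric Function `(labels, scores) -> scalar` (default [roc_auc()]).
#' @param n_boot Number of bootstrap replicates (default 1000).
#' @param level Confidence level (default 0.95).
#' @param seed Integer seed.
#' @return Named vector `c(low, high)` with attribute `"replicates"`.
#' @export
bootstrap_ci <- function(labels, scores, metric = roc_auc, n_boot = 1000L,
                         level = 0.95, seed = 1L) {
  y <- as_binary_labels(labels)
  metric(labels, scores) # must be computable on the full sample
  idx_pos <- which(y); idx_neg <- which(!y)
  resample <- function(idx) idx[sample.int(length(idx), length(idx), replace = TRUE)]
  stats <- withr::with_seed(seed, {
    vapply(seq_len(n_boot), function(b) {
      take <- c(resample(idx_pos), resample(idx_neg))
      metric(labels[take], scores[take])
    }, numeric(1))
  })
  alpha <- (1 - level) / 2
  ci <- unname(quantile(stats, c(alpha, 1 - alpha)))
  out <- c(low = ci[1], high = ci[2])
  attr(out, "replicates") <- n_boot
  out
}

#' Best classification cutoff by Youden's J
#'
#' Scans the midpoints between consecutive distinct score values (plus the
#' extremes) and returns the cutoff maximizing J = sensitivity +
#' specificity - 1, ties resolved toward the lower cutoff. Calls are
#' positive at `score >= cutoff`.
#'
#' @inheritParams roc_auc
#' @return The selected cutoff.
#' @export
best_cutoff <- function(labels, scores) {
  y <- as_binary_labels(labels)
  if (!any(y) || all(y)) abort("both classes must be present")
  u <- sort(unique(scores))
  cands <- if (length(u) == 1L) u else (head(u, -1) + tail(u, -1)) / 2
  j <- vapply(cands, function(ct) {
    call_pos <- scores >= ct
    sum(call_pos & y) / sum(y) + sum(!call_pos & !y) / sum(!y) - 1
  }, numeric(1))
  cands[which.max(j)] # which.max takes the first (lowest) maximizer
}

#' Confusion-matrix metrics
#'
#' Accuracy, precision, recall and F1 with oligodendroglioma as the
#' positive class. Zero-denominator cases return 0 with a warning.
#'
#' @param labels True labels (see [roc_auc()] for encodings).
#' @param calls Predicted labels, same encoding.
#' @return One-row tibble with `accuracy`, `precision`, `recall`, `f1`.
#' @export
confusion_metrics <- function(labels, calls) {
  y <- as_binary_labels(labels)
  p <- as_binary_labels(calls)
  if (length(y) != length(p)) abort("`labels` and `calls` must align")
  tp <- sum(p & y); fp <- sum(p & !y); fn <- sum(!p & y); tn <- sum(!p & !y)
  safe_div <- function(num, den, what) {
    if (den == 0) {
      warn(sprintf("%s undefined (zero denominator); returning 0", what))
      0
    } else num / den
  }
  precision <- safe_div(tp, tp + fp, "precision")
  recall <- safe_div(tp, tp + fn, "recall")
  f1 <- safe_div(2 * precision * recall, precision + recall, "F1")
  tibble::tibble(accuracy = (tp + tn) / length(y),
                 precision = precision, recall = recall, f1 = f1)
}

#' Instance-localization AUC of planted tumor patches
#'
#' Ranks each patch of the arm-deleted slides by the deviation of its raw
#' score from the median score, planted tumor patches being the positive
#' class and the remaining (background) patches of those slides the
#' negatives. The median is taken over the scores pooled across *all*
#' supplied slides: on arm-intact slides every patch scores like normal
#' tissue, so the pooled median estimates the normal-tissue score level.
#' (A per-slide median would sit inside the tumor mode whenever tumor
#' purity exceeds 0.5 and invert the ranking.)
#'
#' @param bags Named list of [feature_bag()]s.
#' @param truth Tibble with `slide_id`, the per-arm deletion flag
#'   (`deleted_1p`/`deleted_19q`) and list-column `tumor_patches`.
#' @param params Fitted `fc_params` (or `fc_estimator`) for the arm.
#' @param arm `"1p"` or `"19q"`.
#' @return AUC of planted vs background patches.
#' @export
localization_auc <- function(bags, truth, params, arm = c("1p", "19q")) {
  arm <- rlang::arg_match(arm)
  if (inherits(params, "fc_estimator")) params <- params$params
  del_col <- paste0("deleted_", arm)
  if (!any(truth[[del_col]])) abort("no deleted slides to localize in")
  pooled <- purrr::list_rbind(purrr::map(truth$slide_id, function(id) {
    b <- bags[[id]]
    s <- score_patches(b, params)
    planted <- seq_len(nrow(b$features)) %in%
      truth$tumor_patches[[match(id, truth$slide_id)]]
    tibble::tibble(score = s, planted = planted,
                   deleted = truth[[del_col]][match(id, truth$slide_id)])
  }))
  extremity <- abs(pooled$score - median(pooled$score))
  roc_auc(pooled$planted[pooled$deleted], extremity[pooled$deleted])
}
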