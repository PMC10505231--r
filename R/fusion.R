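## Fusing the two arm-level FC estimates into an oligodendroglioma
## probability: logistic regression (sigmoid of a linear combination of
## fc_1p and fc_19q), trained by minimizing binary cross-entropy. This
## mirrors how clinicians interpret 1p and 19q FISH jointly.

#' Fit the logistic fusion of 1p and 19q FC estimates
#'
#' Maximizes the binomial log-likelihood (equivalently minimizes binary
#' cross-entropy) by iteratively reweighted least squares with a small L2
#' ridge (default 1e-6) so perfectly separable cohorts still yield a
#' finite, converged fit. Label encoding: oligodendroglioma = 1.
#'
#' @param data Data frame with columns `fc_1p`, `fc_19q` (the slide-level
#'   estimates; columns `fc_1p_hat`/`fc_19q_hat` are also accepted) and a
#'   label column.
#' @param label Name of the label column; values either logical/0-1 or the
#'   strings `"oligodendroglioma"`/`"astrocytoma"`.
#' @param ridge L2 penalty on the coefficients (not the intercept).
#' @param max_iter,tol IRLS iteration cap and gradient-norm convergence
#'   tolerance.
#' @return An object of class `fusion_fit` with elements `coef_1p`,
#'   `coef_19q`, `intercept`, `cutoff` (0.5 until re-set), and fit metadata.
#' @export
train_logistic <- function(data, label = "tumor_type", ridge = 1e-6,
                           max_iter = 100L, tol = 1e-6) {
  x1 <- data[["fc_1p"]] %||% data[["fc_1p_hat"]]
  x2 <- data[["fc_19q"]] %||% data[["fc_19q_hat"]]
  if (is.null(x1) || is.null(x2)) abort("`data` needs fc_1p/fc_19q (or *_hat) columns")
  y <- data[[label]]
  if (is.character(y) || is.factor(y)) y <- as.character(y) == "oligodendroglioma"
  y <- as.numeric(y)
  if (length(unique(y)) < 2L) {
    abort("degenerate fit: both tumor types must be present")
  }
  X <- cbind(1, x1, x2)
  beta <- c(0, 0, 0)
  pen <- diag(c(0, ridge, ridge))
  converged <- FALSE
  for (it in seq_len(max_iter)) {
    eta <- drop(X %*% beta)
    p <- plogis(eta)
    g <- drop(crossprod(X, y - p)) - drop(pen %*% beta)
    if (sqrt(sum(g^2)) < tol) { converged <- TRUE; break }
    w <- pmax(p * (1 - p), 1e-10)
    H <- crossprod(X, X * w) + pen
    beta <- beta + solve(H, g)
  }
  structure(list(intercept = beta[1], coef_1p = beta[2], coef_19q = beta[3],
                 cutoff = 0.5, converged = converged, iterations = it,
                 n = length(y), ridge = ridge),
            class = "fusion_fit")
}

#' @export
print.fusion_fit <- function(x, ...) {
  cat(sprintf("<fusion_fit> logit(p_oligo) = %.3f + %.3f*fc_1p + %.3f*fc_19q (cutoff %.3f)\n",
              x$intercept, x$coef_1p, x$coef_19q, x$cutoff))
  invisible(x)
}

#' @rdname train_logistic
#' @param x A `fusion_fit`.
#' @param ... Unused.
#' @exportS3Method generics::tidy
tidy.fusion_fit <- function(x, ...) {
  tibble::tibble(term = c("(Intercept)", "fc_1p", "fc_19q"),
                 estimate = c(x$intercept, x$coef_1p, x$coef_19q))
}

#' @rdname train_logistic
#' @exportS3Method generics::glance
glance.fusion_fit <- function(x, ...) {
  tibble::tibble(n = x$n, converged = x$converged, iterations = x$iterations,
                 cutoff = x$cutoff)
}

#' Oligodendroglioma probability from the two FC estimates
#'
#' `sigmoid(intercept + coef_1p * fc_1p + coef_19q * fc_19q)`; strictly in
#' (0, 1) for finite inputs.
#'
#' @param fc_1p,fc_19q Slide-level FC estimates (vectorized).
#' @param params A [train_logistic()] fit (or any list with `intercept`,
#'   `coef_1p`, `coef_19q`).
#' @return Numeric vector of probabilities.
#' @export
predict_proba <- function(fc_1p, fc_19q, params) {
  stopifnot(all(is.finite(fc_1p)), all(is.finite(fc_19q)))
  plogis(params$intercept + params$coef_1p * fc_1p + params$coef_19q * fc_19q)
}

#' Dichotomize an oligodendroglioma probability
#'
#' Calls oligodendroglioma iff `prob >= cutoff` (ties go to
#' oligodendroglioma, a fixed deterministic convention).
#'
#' @param prob Probability vector in \[0, 1\].
#' @param cutoff Decision cutoff in (0, 1).
#' @return Character vector of `"astrocytoma"`/`"oligodendroglioma"`.
#' @export
classify <- function(prob, cutoff = 0.5) {
  if (!is.numeric(cutoff) || length(cutoff) != 1L || cutoff <= 0 || cutoff >= 1) {
    abort("`cutoff` must lie strictly inside (0, 1)")
  }
  stopifnot(all(prob >= 0 & prob <= 1))
  ifelse(prob >= cutoff, "oligodendroglioma", "astrocytoma")
}

#' Attach fused oligodendroglioma probabilities to a prediction table
#'
#' @param predictions Tibble from [predict_cohort()] (columns `fc_1p_hat`,
#'   `fc_19q_hat`).
#' @param fit A [train_logistic()] fit.
#' @return `predictions` with `prob_oligo` filled in.
#' @export
fuse_predictions <- function(predictions, fit) {
  dplyr::mutate(predictions,
                prob_oligo = predict_proba(.data$fc_1p_hat, .data$fc_19q_hat, fit))
}
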