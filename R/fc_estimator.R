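## The weakly-supervised FC regressor. Each patch gets a raw linear score;
## the N highest and N lowest scores (min-max selection) are fed to a
## 200-100-1 MLP with a sigmoid after every layer, yielding a slide-level
## fold-change estimate in (0,1) trained against NGS labels with MSE.

#' Initialize parameters for one chromosome-arm FC estimator
#'
#' MLP weights are drawn from zero-mean Gaussians scaled by 1/sqrt(fan-in);
#' biases start at zero. The patch scorer starts at exactly zero: a single
#' linear unit needs no symmetry breaking, and a random initial direction
#' would persist as score noise (the weight decay is far too small to
#' remove it within a typical training budget), degrading patch-level
#' interpretability. Deterministic in `seed`.
#'
#' @param feature_dim Patch feature dimension D.
#' @param n_extreme N, the number of highest and of lowest patch scores
#'   fed to the MLP (input length 2N).
#' @param arm `"1p"` or `"19q"`.
#' @param hidden Hidden layer widths of the MLP (default `c(200, 100)`).
#' @param seed Integer seed for the initialization.
#' @return An object of class `fc_params`.
#' @export
fc_params_init <- function(feature_dim, n_extreme = 100L, arm = c("1p", "19q"),
                           hidden = c(200L, 100L), seed = 1L) {
  arm <- rlang::arg_match(arm)
  D <- assert_count(feature_dim, "feature_dim")
  N <- assert_count(n_extreme, "n_extreme")
  stopifnot(length(hidden) == 2L)
  h1 <- as.integer(hidden[1]); h2 <- as.integer(hidden[2])
  withr::with_seed(seed, {
    params <- list(
      scorer_w = numeric(D),
      scorer_b = 0,
      W1 = matrix(rnorm(h1 * 2 * N) / sqrt(2 * N), nrow = h1),
      b1 = numeric(h1),
      W2 = matrix(rnorm(h2 * h1) / sqrt(h1), nrow = h2),
      b2 = numeric(h2),
      W3 = matrix(rnorm(h2) / sqrt(h2), nrow = 1L),
      b3 = 0
    )
  })
  structure(c(params, list(arm = arm, n_extreme = N, feature_dim = D)),
            class = "fc_params")
}

#' @export
print.fc_params <- function(x, ...) {
  cat(sprintf("<fc_params> arm %s: D=%d, N=%d, MLP %d-%d-1\n", x$arm,
              x$feature_dim, x$n_extreme, nrow(x$W1), nrow(x$W2)))
  invisible(x)
}

#' Score every patch of a bag with the linear patch scorer
#'
#' Raw (unbounded) per-patch scores `w . f_i + b`. A sigmoid is applied only
#' when scores are interpreted as patch-level FC values (see
#' [patch_fc_values()]); selection operates on the raw scores, which a
#' monotone transform would rank identically.
#'
#' @param bag A [feature_bag()] or a P x D feature matrix.
#' @param params An [fc_params_init()] object.
#' @return Numeric vector of P patch scores.
#' @export
score_patches <- function(bag, params) {
  feat <- if (inherits(bag, "feature_bag")) bag$features else bag
  assert_finite_matrix(feat, "features")
  if (ncol(feat) != length(params$scorer_w)) {
    abort(sprintf("feature dimension %d does not match scorer dimension %d",
                  ncol(feat), length(params$scorer_w)))
  }
  drop(feat %*% params$scorer_w) + params$scorer_b
}

#' Select the N highest and N lowest patch scores
#'
#' Returns the N largest scores in descending order followed by the N
#' smallest, also in descending order. Ties are broken toward the lower
#' patch index. When a bag has fewer than 2N patches the sorted score list
#' is recycled (each value repeated `ceiling(2N/P)` times, preserving the
#' descending order) so the output always has length 2N and keeps the
#' score-scale statistics of the bag.
#'
#' @param scores Numeric vector of patch scores (length >= 1).
#' @param n_extreme N, the number of scores to keep per side.
#' @param with_indices If `TRUE`, also return the selected patch indices.
#' @return Numeric vector of length 2N, or a list with `values` and
#'   `indices` when `with_indices = TRUE`.
#' @export
select_extremes <- function(scores, n_extreme, with_indices = FALSE) {
  if (length(scores) < 1L) abort("`scores` must be non-empty")
  if (anyNA(scores) || any(!is.finite(scores))) abort("`scores` must be finite")
  N <- assert_count(n_extreme, "n_extreme")
  P <- length(scores)
  ord <- order(-scores, seq_len(P)) # descending, ties to lower index
  if (P >= 2L * N) {
    bottom <- order(scores, seq_len(P))[seq_len(N)] # N smallest, ties to lower index
    bottom <- bottom[order(-scores[bottom], bottom)] # presented descending
    idx <- c(ord[seq_len(N)], bottom)
  } else {
    reps <- ceiling(2L * N / P)
    pool <- rep(ord, each = reps) # descending order preserved
    idx <- c(pool[seq_len(N)], tail(pool, N))
  }
  if (with_indices) list(values = scores[idx], indices = idx) else scores[idx]
}

## forward pass of the 200-100-1 MLP; optionally keeps intermediates for
## backprop and applies inverted dropout to the layer inputs
mlp_forward <- function(selected, params, dropout_p = 0, keep = FALSE) {
  x <- selected
  if (dropout_p > 0) {
    m1 <- (runif(length(x)) >= dropout_p) / (1 - dropout_p)
    x <- x * m1
  } else m1 <- NULL
  h1 <- sigmoid(drop(params$W1 %*% x) + params$b1)
  h1d <- h1
  if (dropout_p > 0) {
    m2 <- (runif(length(h1)) >= dropout_p) / (1 - dropout_p)
    h1d <- h1 * m2
  } else m2 <- NULL
  h2 <- sigmoid(drop(params$W2 %*% h1d) + params$b2)
  y <- sigmoid(drop(params$W3 %*% h2) + params$b3)
  if (!keep) return(y)
  list(y = y, x = x, h1 = h1, h1d = h1d, h2 = h2, m1 = m1, m2 = m2)
}

#' Aggregate selected extreme scores into a slide-level FC estimate
#'
#' Three-layer MLP with a sigmoid after each layer; the output is therefore
#' strictly inside (0, 1). No dropout is applied at inference.
#'
#' @param selected Numeric vector of length 2N from [select_extremes()].
#' @param params An [fc_params_init()] object.
#' @return A single FC estimate in (0, 1).
#' @export
aggregate_slide_fc <- function(selected, params) {
  if (length(selected) != ncol(params$W1)) {
    abort(sprintf("`selected` has length %d but the MLP expects %d",
                  length(selected), ncol(params$W1)))
  }
  unname(mlp_forward(selected, params))
}

#' Predict slide-level 1p and 19q FC values for one bag
#'
#' Composition of patch scoring, min-max selection and MLP aggregation for
#' each arm. Invariant to the ordering of patch rows (selection sorts).
#'
#' @param bag A [feature_bag()].
#' @param params_1p,params_19q Fitted [fc_params_init()] objects per arm.
#' @param n_extreme N; defaults to the value stored in `params_1p`.
#' @return A list of class `slide_prediction`: one-row tibble `prediction`
#'   (`slide_id`, `fc_1p_hat`, `fc_19q_hat`, `prob_oligo` = `NA` until
#'   fusion) plus per-patch score vectors `patch_scores_1p`,
#'   `patch_scores_19q` aligned with the bag rows.
#' @export
predict_slide <- function(bag, params_1p, params_19q,
                          n_extreme = params_1p$n_extreme) {
  s1 <- score_patches(bag, params_1p)
  s2 <- score_patches(bag, params_19q)
  fc1 <- aggregate_slide_fc(select_extremes(s1, n_extreme), params_1p)
  fc2 <- aggregate_slide_fc(select_extremes(s2, n_extreme), params_19q)
  structure(
    list(
      prediction = tibble::tibble(
        slide_id = if (inherits(bag, "feature_bag")) bag$slide_id else NA_character_,
        fc_1p_hat = fc1, fc_19q_hat = fc2, prob_oligo = NA_real_
      ),
      patch_scores_1p = s1, patch_scores_19q = s2
    ),
    class = "slide_prediction"
  )
}

#' Mean squared error between FC predictions and labels
#'
#' @param predictions,labels Numeric vectors of equal length >= 1.
#' @return Mean of squared differences (>= 0).
#' @export
mse_loss <- function(predictions, labels) {
  if (length(predictions) != length(labels) || length(labels) < 1L) {
    abort("`predictions` and `labels` must have equal length >= 1")
  }
  mean((predictions - labels)^2)
}
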