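## Training of the FC estimator: Adam on the mean squared error between the
## slide-level estimate and the NGS fold-change label, with inverted dropout
## on the inputs of the aggregator MLP's layers 1 and 2 (masking the patch
## features themselves would corrupt the scores that min-max selection
## ranks). Gradients flow through the min-max selection to the selected
## patches only (the selection itself is piecewise constant).

#' Training configuration for an FC estimator
#'
#' Defaults follow the CHOWDER-style recipe: Adam with learning rate 1e-4
#' and weight decay 5e-4, dropout 0.5 on the linear layers, and N = 100
#' extreme patches per side.
#'
#' @param n_extreme N, extreme patches per side (MLP input length 2N).
#' @param learning_rate Adam step size.
#' @param weight_decay L2 penalty added to the gradient (decoupled from the
#'   loss value that is reported).
#' @param dropout_p Dropout probability on the inputs of the aggregator
#'   MLP's first and second linear layers, training only. The patch scorer
#'   is left un-dropped: masking patch features would randomize the scores
#'   that the min-max selection ranks.
#' @param max_epochs Maximum training epochs.
#' @param batch_size Slides per optimizer step. Bags have variable length,
#'   so the usual multiple-instance practice of one bag per step is the
#'   default; gradients are averaged over the batch when larger.
#' @param early_stop_patience Epochs without validation improvement before
#'   stopping (ignored when no validation set is given).
#' @param hidden MLP hidden widths.
#' @param seed Seed controlling initialization, dropout and shuffling.
#' @return A list of class `train_config`.
#' @export
train_config <- function(n_extreme = 100L, learning_rate = 1e-4,
                         weight_decay = 5e-4, dropout_p = 0.5,
                         max_epochs = 100L, batch_size = 1L,
                         early_stop_patience = 10L, hidden = c(200L, 100L),
                         seed = 1L) {
  stopifnot(learning_rate > 0, weight_decay >= 0,
            dropout_p >= 0, dropout_p < 1)
  assert_count(n_extreme, "n_extreme")
  assert_count(max_epochs, "max_epochs")
  assert_count(batch_size, "batch_size")
  structure(list(n_extreme = as.integer(n_extreme),
                 learning_rate = learning_rate, weight_decay = weight_decay,
                 dropout_p = dropout_p, max_epochs = as.integer(max_epochs),
                 batch_size = as.integer(batch_size),
                 early_stop_patience = as.integer(early_stop_patience),
                 hidden = as.integer(hidden), seed = as.integer(seed)),
            class = "train_config")
}

## resolve labels to a numeric vector aligned with bags
label_vector <- function(labels, bags, arm) {
  if (is.numeric(labels)) {
    if (length(labels) != length(bags)) {
      abort("numeric `labels` must align with `bags`")
    }
    return(labels)
  }
  col <- paste0("fc_", arm)
  if (!is.data.frame(labels) || !all(c("slide_id", col) %in% names(labels))) {
    abort(sprintf("`labels` must be numeric or a data frame with slide_id and %s", col))
  }
  ids <- purrr::map_chr(bags, "slide_id")
  pos <- match(ids, labels$slide_id)
  if (anyNA(pos)) abort("every bag needs a label row (slide_id mismatch)")
  labels[[col]][pos]
}

## forward + backward for one slide; returns loss and gradient contribution
slide_grad <- function(feat, label, params, N, dropout_p) {
  s <- drop(feat %*% params$scorer_w) + params$scorer_b
  sel <- select_extremes(s, N, with_indices = TRUE)
  fwd <- mlp_forward(sel$values, params, dropout_p = dropout_p, keep = TRUE)
  y <- fwd$y
  loss <- (y - label)^2
  dy <- 2 * (y - label)
  da3 <- dy * y * (1 - y)
  dh2 <- drop(t(params$W3)) * da3
  da2 <- dh2 * fwd$h2 * (1 - fwd$h2)
  dh1d <- drop(crossprod(params$W2, da2))
  dh1 <- if (!is.null(fwd$m2)) dh1d * fwd$m2 else dh1d
  da1 <- dh1 * fwd$h1 * (1 - fwd$h1)
  dxd <- drop(crossprod(params$W1, da1))
  dx <- if (!is.null(fwd$m1)) dxd * fwd$m1 else dxd
  feat_sel <- feat[sel$indices, , drop = FALSE]
  list(
    loss = loss,
    g = list(
      scorer_w = drop(crossprod(feat_sel, dx)),
      scorer_b = sum(dx),
      W1 = tcrossprod(da1, fwd$x),
      b1 = da1,
      W2 = tcrossprod(da2, fwd$h1d),
      b2 = da2,
      W3 = matrix(da3 * fwd$h2, nrow = 1L),
      b3 = da3
    )
  )
}

trainable <- c("scorer_w", "scorer_b", "W1", "b1", "W2", "b2", "W3", "b3")

adam_step <- function(params, grads, state, lr, wd) {
  b1 <- 0.9; b2 <- 0.999; eps <- 1e-8
  state$t <- state$t + 1L
  for (nm in trainable) {
    g <- grads[[nm]] + wd * params[[nm]]
    state$m[[nm]] <- b1 * state$m[[nm]] + (1 - b1) * g
    state$v[[nm]] <- b2 * state$v[[nm]] + (1 - b2) * g^2
    mhat <- state$m[[nm]] / (1 - b1^state$t)
    vhat <- state$v[[nm]] / (1 - b2^state$t)
    params[[nm]] <- params[[nm]] - lr * mhat / (sqrt(vhat) + eps)
  }
  list(params = params, state = state)
}

## validation MSE (no dropout)
eval_mse <- function(bags, labels, params, N) {
  preds <- purrr::map_dbl(bags, function(b) {
    s <- score_patches(b, params)
    aggregate_slide_fc(select_extremes(s, N), params)
  })
  mse_loss(preds, labels)
}

#' Train one chromosome-arm FC estimator
#'
#' Minimizes the mean squared error between the slide-level FC estimate and
#' the slide labels with Adam (learning rate and weight decay from
#' `config`), applying dropout to the linear layers during training only.
#' Labels must lie in (0, 1.5]; labels above 1 are clipped to 0.999 with a
#' warning because the final sigmoid cannot reach 1. The parameter snapshot
#' with the best validation loss is returned (best training loss when no
#' validation set is supplied). Deterministic given `config$seed`.
#'
#' @param bags List of [feature_bag()]s for training.
#' @param labels Numeric FC labels aligned with `bags`, or a tibble with
#'   columns `slide_id` and `fc_1p`/`fc_19q`.
#' @param arm `"1p"` or `"19q"`.
#' @param val_bags,val_labels Optional validation set (used for early
#'   stopping and snapshot selection).
#' @param config A [train_config()].
#' @return An object of class `fc_estimator`: fitted `params`, the
#'   `config`, a per-epoch `log` tibble and the selected `best_epoch`.
#' @export
train_fc_estimator <- function(bags, labels, arm = c("1p", "19q"),
                               val_bags = NULL, val_labels = NULL,
                               config = train_config()) {
  arm <- rlang::arg_match(arm)
  if (length(bags) < 1L) abort("need at least one training slide")
  y <- label_vector(labels, bags, arm)
  if (any(y <= 0) || any(y > 1.5)) abort("labels must lie in (0, 1.5]")
  if (any(y > 1)) {
    warn(sprintf("%d label(s) above 1 clipped to 0.999 (sigmoid output is open at 1)",
                 sum(y > 1)))
    y[y > 1] <- 0.999
  }
  has_val <- !is.null(val_bags) && length(val_bags) > 0
  if (has_val) {
    yv <- label_vector(val_labels, val_bags, arm)
    yv[yv > 1] <- 0.999
  }
  D <- ncol(bags[[1]]$features)
  N <- config$n_extreme
  params <- fc_params_init(D, N, arm, hidden = config$hidden,
                           seed = derive_seed(config$seed, if (arm == "1p") 101L else 102L))
  state <- list(t = 0L,
                m = purrr::map(params[trainable], ~ .x * 0),
                v = purrr::map(params[trainable], ~ .x * 0))
  feats <- purrr::map(bags, "features")
  n <- length(bags)
  log_rows <- vector("list", config$max_epochs)
  best <- list(loss = Inf, params = params, epoch = 0L)
  stall <- 0L
  withr::with_seed(derive_seed(config$seed, if (arm == "1p") 201L else 202L), {
    for (epoch in seq_len(config$max_epochs)) {
      ord <- sample.int(n)
      epoch_loss <- 0
      i <- 1L
      while (i <= n) {
        batch <- ord[seq.int(i, min(i + config$batch_size - 1L, n))]
        grads <- NULL
        for (j in batch) {
          sg <- slide_grad(feats[[j]], y[j], params, N, config$dropout_p)
          epoch_loss <- epoch_loss + sg$loss
          if (is.null(grads)) {
            grads <- sg$g
          } else {
            for (nm in trainable) grads[[nm]] <- grads[[nm]] + sg$g[[nm]]
          }
        }
        for (nm in trainable) grads[[nm]] <- grads[[nm]] / length(batch)
        if (any(!is.finite(grads$scorer_w))) {
          abort("non-finite gradient: training diverged; last good snapshot kept")
        }
        upd <- adam_step(params, grads, state, config$learning_rate,
                         config$weight_decay)
        params <- upd$params
        state <- upd$state
        i <- i + config$batch_size
      }
      train_loss <- epoch_loss / n
      val_loss <- if (has_val) eval_mse(val_bags, yv, params, N) else NA_real_
      log_rows[[epoch]] <- tibble::tibble(epoch = epoch, train_loss = train_loss,
                                          val_loss = val_loss)
      monitor <- if (has_val) val_loss else train_loss
      if (is.finite(monitor) && monitor < best$loss) {
        best <- list(loss = monitor, params = params, epoch = epoch)
        stall <- 0L
      } else {
        stall <- stall + 1L
      }
      if (has_val && stall >= config$early_stop_patience) break
    }
  })
  structure(
    list(params = best$params, config = config, arm = arm,
         log = purrr::list_rbind(purrr::compact(log_rows)),
         best_epoch = best$epoch, n_train = n,
         extractor_id = bags[[1]]$extractor_id %||% "unknown"),
    class = "fc_estimator"
  )
}

#' @export
print.fc_estimator <- function(x, ...) {
  cat(sprintf("<fc_estimator> arm %s: trained on %d slides, best epoch %d\n",
              x$arm, x$n_train, x$best_epoch))
  invisible(x)
}

#' @rdname train_fc_estimator
#' @param x A fitted `fc_estimator`.
#' @param ... Unused.
#' @exportS3Method generics::tidy
tidy.fc_estimator <- function(x, ...) x$log

#' @rdname train_fc_estimator
#' @exportS3Method generics::glance
glance.fc_estimator <- function(x, ...) {
  tibble::tibble(
    arm = x$arm, n_train = x$n_train, best_epoch = x$best_epoch,
    epochs_run = nrow(x$log),
    train_loss = x$log$train_loss[match(x$best_epoch, x$log$epoch)],
    val_loss = x$log$val_loss[match(x$best_epoch, x$log$epoch)]
  )
}

#' Predict slide-level FC values for a cohort of bags
#'
#' @param bags Named list of [feature_bag()]s.
#' @param fit_1p,fit_19q Fitted [train_fc_estimator()] objects (or bare
#'   `fc_params`).
#' @return A tibble with one row per slide: `slide_id`, `fc_1p_hat`,
#'   `fc_19q_hat`, `prob_oligo` (`NA` until [fuse_predictions()]).
#' @export
predict_cohort <- function(bags, fit_1p, fit_19q) {
  p1 <- if (inherits(fit_1p, "fc_estimator")) fit_1p$params else fit_1p
  p19 <- if (inherits(fit_19q, "fc_estimator")) fit_19q$params else fit_19q
  purrr::list_rbind(purrr::map(bags, function(b) {
    predict_slide(b, p1, p19)$prediction
  }))
}
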