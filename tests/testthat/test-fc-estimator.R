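# min-max MIL estimator: scoring, selection, aggregation, training

test_that("patch scoring equals the per-row dot-product oracle", {
  bag <- random_bag(P = 50, D = 8, seed = 2)
  p <- random_fc_params(D = 8, seed = 2)
  got <- score_patches(bag, p)
  oracle <- numeric(50)
  for (i in 1:50) {
    acc <- p$scorer_b
    for (j in 1:8) acc <- acc + p$scorer_w[j] * bag$features[i, j]
    oracle[i] <- acc
  }
  expect_equal(got, oracle, tolerance = 1e-10)
  # zero weights give the bias everywhere; one-hot features pick one weight
  pz <- p; pz$scorer_w <- rep(0, 8); pz$scorer_b <- 0.7
  expect_equal(score_patches(bag, pz), rep(0.7, 50))
  e3 <- matrix(0, 1, 8); e3[1, 3] <- 1
  expect_equal(score_patches(e3, p), p$scorer_w[3] + p$scorer_b)
  expect_error(score_patches(random_bag(P = 5, D = 4), p), "dimension")
})

test_that("extreme selection matches a full-sort oracle, including ties", {
  expect_equal(select_extremes(c(0.9, 0.1, 0.5), 1), c(0.9, 0.1))
  withr::with_seed(8, {
    for (rep in 1:50) {
      P <- sample(5:200, 1)
      N <- sample.int(floor(P / 2), 1)
      scores <- sample(round(rnorm(P), 2), P, replace = TRUE) # many ties
      got <- select_extremes(scores, N)
      sorted <- sort(scores, decreasing = TRUE)
      expect_identical(got, c(head(sorted, N), tail(sorted, N)))
    }
  })
  # one big instance at the default-style scale
  withr::with_seed(9, {
    scores <- rnorm(5000)
    got <- select_extremes(scores, 100)
    expect_length(got, 200)
    sorted <- sort(scores, decreasing = TRUE)
    expect_equal(got, c(head(sorted, 100), tail(sorted, 100)))
  })
})

test_that("selection ties break toward the lower patch index", {
  sel <- select_extremes(c(1, 1, 0, 0), 1, with_indices = TRUE)
  expect_equal(sel$indices, c(1L, 3L))
})

test_that("bags smaller than 2N recycle the sorted scores deterministically", {
  # P = 3, N = 2: each sorted value repeated ceiling(4/3) = 2 times,
  # top block takes the first N of the pool, bottom block the last N
  got <- select_extremes(c(0.2, 0.9, 0.5), 2)
  expect_length(got, 4)
  expect_equal(got, c(0.9, 0.9, 0.2, 0.2))
  expect_true(all(got %in% c(0.2, 0.9, 0.5))) # scale statistics preserved
})

test_that("MLP aggregation is sigmoid-bounded and matches longhand arithmetic", {
  # all-zero parameters: sigmoid(0) at every layer -> exactly 0.5
  p0 <- fc_params_init(4, 2, "1p", hidden = c(6L, 4L), seed = 1)
  for (nm in c("scorer_w", "W1", "b1", "W2", "b2", "W3", "b3")) p0[[nm]] <- p0[[nm]] * 0
  expect_identical(aggregate_slide_fc(rep(2, 4), p0), 0.5)
  # random parameters always land strictly inside (0, 1)
  withr::with_seed(3, {
    for (i in 1:50) {
      p <- fc_params_init(4, 2, "1p", hidden = c(6L, 4L), seed = i)
      p$scorer_w <- rnorm(4)
      out <- aggregate_slide_fc(rnorm(4, sd = 5), p)
      expect_true(out > 0 && out < 1)
    }
  })
  # miniature 1-unit-per-layer network vs longhand forward pass
  pm <- fc_params_init(2, 1, "1p", hidden = c(1L, 1L), seed = 1)
  pm$W1 <- matrix(c(0.5, -0.25), nrow = 1); pm$b1 <- 0.1
  pm$W2 <- matrix(2, 1, 1); pm$b2 <- -0.3
  pm$W3 <- matrix(-1.5, 1, 1); pm$b3 <- 0.2
  x <- c(0.8, -0.4)
  h1 <- plogis(0.5 * 0.8 + (-0.25) * (-0.4) + 0.1)
  h2 <- plogis(2 * h1 - 0.3)
  expect_equal(aggregate_slide_fc(x, pm), plogis(-1.5 * h2 + 0.2), tolerance = 1e-12)
  expect_error(aggregate_slide_fc(rep(0, 3), pm), "expects")
})

test_that("slide prediction is invariant to patch order and retains scores", {
  bag <- random_bag(P = 60, D = 8, seed = 4)
  p1 <- random_fc_params(D = 8, N = 5, seed = 5)
  p19 <- random_fc_params(D = 8, N = 5, seed = 6)
  base <- predict_slide(bag, p1, p19, n_extreme = 5)
  expect_length(base$patch_scores_1p, 60)
  withr::with_seed(10, {
    for (k in 1:5) {
      perm <- sample.int(60)
      shuffled <- feature_bag(bag$slide_id, bag$features[perm, ],
                              bag$coords, extractor_id = "test")
      got <- predict_slide(shuffled, p1, p19, n_extreme = 5)
      expect_identical(got$prediction$fc_1p_hat, base$prediction$fc_1p_hat)
      expect_identical(got$prediction$fc_19q_hat, base$prediction$fc_19q_hat)
    }
  })
})

test_that("uniform score shifts leave the selected membership unchanged", {
  withr::with_seed(12, {
    for (k in 1:20) {
      s <- rnorm(80)
      a <- select_extremes(s, 10, with_indices = TRUE)
      b <- select_extremes(s + 3.7, 10, with_indices = TRUE)
      expect_identical(a$indices, b$indices)
    }
  })
})

test_that("mse loss is the mean of squared differences", {
  expect_identical(mse_loss(c(1, 2, 3), c(1, 2, 3)), 0)
  expect_identical(mse_loss(0.5, 1.0), 0.25)
  withr::with_seed(14, {
    a <- rnorm(30); b <- rnorm(30)
    oracle <- 0
    for (i in 1:30) oracle <- oracle + (a[i] - b[i])^2
    expect_equal(mse_loss(a, b), oracle / 30, tolerance = 1e-12)
  })
  expect_error(mse_loss(1:3, 1:2), "length")
})

test_that("training reduces the loss and honors the configured recipe", {
  co <- tiny_cohort(n = 6, seed = 21)
  cfg <- quick_train_config(max_epochs = 30L)
  expect_equal(train_config()$learning_rate, 1e-4)
  expect_equal(train_config()$weight_decay, 5e-4)
  expect_equal(train_config()$dropout_p, 0.5)
  expect_equal(train_config()$n_extreme, 100L)
  fit <- suppressWarnings(
    train_fc_estimator(co$bags[1], co$labels[1, ], "1p", config = cfg))
  expect_lt(tail(fit$log$train_loss, 1), fit$log$train_loss[1])
  # determinism: identical config + data -> identical parameters
  fit2 <- suppressWarnings(
    train_fc_estimator(co$bags[1], co$labels[1, ], "1p", config = cfg))
  expect_identical(fit$params$W1, fit2$params$W1)
  expect_identical(fit$params$scorer_w, fit2$params$scorer_w)
  # tidy/glance interfaces
  expect_named(tidy(fit), c("epoch", "train_loss", "val_loss"))
  expect_equal(glance(fit)$arm, "1p")
})

test_that("labels above 1 are clipped with a warning and bad inputs rejected", {
  co <- tiny_cohort(n = 4, seed = 22)
  labels <- c(1.2, 0.7, 0.9, 1.0)
  expect_warning(
    train_fc_estimator(co$bags, labels, "1p",
                       config = quick_train_config(max_epochs = 1L)),
    "clipped")
  expect_error(train_fc_estimator(list(), numeric(0), "1p"), "at least one")
  expect_error(
    train_fc_estimator(co$bags, c(2, 0.7, 0.9, 1), "1p",
                       config = quick_train_config(max_epochs = 1L)),
    "1.5")
})
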