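# evaluation metrics: R2, AUC, bootstrap CI, cutoff, confusion

test_that("R-squared matches the longhand sum-of-squares computation", {
  withr::with_seed(1, {
    truth <- rnorm(40); pred <- truth + rnorm(40, sd = 0.3)
    ss_res <- 0; ss_tot <- 0; m <- sum(truth) / 40
    for (i in 1:40) {
      ss_res <- ss_res + (truth[i] - pred[i])^2
      ss_tot <- ss_tot + (truth[i] - m)^2
    }
    expect_equal(r_squared(truth, pred), 1 - ss_res / ss_tot, tolerance = 1e-10)
  })
  expect_equal(r_squared(1:10, 1:10), 1.0)
  expect_equal(r_squared(1:10, rep(5.5, 10)), 0.0)
  expect_error(r_squared(rep(2, 5), rnorm(5)), "constant")
  expect_error(r_squared(1:3, 1:2), "length")
})

test_that("R-squared is invariant to a shared affine rescaling", {
  withr::with_seed(2, {
    truth <- runif(30); pred <- truth + rnorm(30, sd = 0.2)
    expect_equal(r_squared(truth, pred),
                 r_squared(3.2 * truth - 1.1, 3.2 * pred - 1.1),
                 tolerance = 1e-10)
  })
})

test_that("AUC equals the all-pairs counting oracle, ties counted half", {
  pair_auc <- function(y, s) {
    pos <- s[y]; neg <- s[!y]
    tot <- 0
    for (p in pos) for (n in neg) {
      tot <- tot + (p > n) + 0.5 * (p == n)
    }
    tot / (length(pos) * length(neg))
  }
  expect_equal(roc_auc(c(0, 0, 1, 1), c(1, 2, 3, 4)), 1.0)
  expect_equal(roc_auc(c(0, 0, 1, 1), c(4, 3, 2, 1)), 0.0)
  withr::with_seed(3, {
    for (i in 1:30) {
      y <- sample(c(TRUE, FALSE), 30, replace = TRUE)
      if (!any(y) || all(y)) next
      s <- sample(round(rnorm(30), 1), 30, replace = TRUE) # ties
      expect_equal(roc_auc(y, s), pair_auc(y, s), tolerance = 1e-12)
    }
  })
  expect_error(roc_auc(rep(1, 5), rnorm(5)), "both classes")
})

test_that("AUC agrees with pROC and obeys the score-negation symmetry", {
  withr::with_seed(4, {
    y <- rep(c(0, 1), each = 25)
    s <- rnorm(50) + y
    expect_equal(roc_auc(y, s),
                 as.numeric(pROC::auc(pROC::roc(y, s, quiet = TRUE))),
                 tolerance = 1e-12)
    expect_equal(roc_auc(y, s) + roc_auc(y, -s), 1.0, tolerance = 1e-12)
  })
})

test_that("bootstrap CI is percentile-based, stratified and deterministic in the seed", {
  withr::with_seed(5, {
    y <- rep(c(0, 1), each = 30)
    s <- rnorm(60) + 1.2 * y
  })
  ci1 <- bootstrap_ci(y, s, n_boot = 200, seed = 9)
  ci2 <- bootstrap_ci(y, s, n_boot = 200, seed = 9)
  expect_identical(ci1, ci2)
  expect_lte(ci1[["low"]], roc_auc(y, s))
  expect_gte(ci1[["high"]], roc_auc(y, s))
  # constant metric -> zero-width interval at that constant
  cc <- bootstrap_ci(y, s, metric = function(l, sc) 0.7, n_boot = 50, seed = 1)
  expect_equal(unname(cc), c(0.7, 0.7), ignore_attr = TRUE)
  # interval narrows with sample size under the same generating process
  withr::with_seed(6, {
    mk <- function(n) {
      y <- rep(c(0, 1), each = n / 2)
      list(y = y, s = rnorm(n) + 1.5 * y)
    }
    small <- mk(50); big <- mk(500)
  })
  w_small <- diff(unname(bootstrap_ci(small$y, small$s, n_boot = 300, seed = 2)))
  w_big <- diff(unname(bootstrap_ci(big$y, big$s, n_boot = 300, seed = 2)))
  expect_lt(w_big, w_small)
})

test_that("best cutoff maximizes Youden's J as an exhaustive scan confirms", {
  # perfectly separated: midpoint of the gap
  expect_equal(best_cutoff(c(0, 0, 1, 1), c(0.1, 0.2, 0.8, 0.9)), 0.5)
  # all scores identical: the single candidate
  expect_equal(best_cutoff(c(0, 1), c(0.4, 0.4)), 0.4)
  scan_oracle <- function(y, s) {
    u <- sort(unique(s))
    cands <- if (length(u) == 1) u else (head(u, -1) + tail(u, -1)) / 2
    best <- -Inf; best_c <- NA
    for (ct in cands) {
      sens <- mean(s[y] >= ct); spec <- mean(s[!y] < ct)
      if (sens + spec - 1 > best) { best <- sens + spec - 1; best_c <- ct }
    }
    best_c
  }
  withr::with_seed(7, {
    for (i in 1:30) {
      y <- sample(c(TRUE, FALSE), 40, replace = TRUE)
      if (!any(y) || all(y)) next
      s <- sample(round(runif(40), 1), 40, replace = TRUE)
      expect_equal(best_cutoff(y, s), scan_oracle(y, s))
    }
  })
})

test_that("confusion metrics follow their standard definitions", {
  all_good <- confusion_metrics(c(1, 1, 0, 0), c(1, 1, 0, 0))
  expect_equal(unlist(all_good), c(accuracy = 1, precision = 1, recall = 1, f1 = 1))
  # TP 9, FP 1, FN 1, TN 9
  y <- rep(c(1, 0), each = 10)
  calls <- c(rep(1, 9), 0, 1, rep(0, 9))
  m <- confusion_metrics(y, calls)
  expect_equal(unlist(m), c(accuracy = 0.9, precision = 0.9, recall = 0.9, f1 = 0.9))
  w <- testthat::capture_warnings(none <- confusion_metrics(c(1, 0), c(0, 0)))
  expect_match(w, "precision", all = FALSE)
  expect_equal(none$precision, 0)
})

test_that("localization AUC recovers planted patches from a signal-aligned scorer", {
  co <- tiny_cohort(n = 8, seed = 31)
  # oracle scorer: weight on the 1p signal axis only
  p <- fc_params_init(12, 4, "1p", hidden = c(6L, 4L), seed = 1)
  p$scorer_w <- c(1, rep(0, 11))
  auc <- localization_auc(co$bags, co$labels, p, "1p")
  expect_gt(auc, 0.75)
  expect_error(localization_auc(co$bags, co$labels[!co$labels$deleted_1p, ], p, "1p"),
               "deleted")
})
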