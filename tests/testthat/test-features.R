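# frozen stub extractor and the feature cache

test_that("stub extractor equals an independently recomputed random projection", {
  px <- simulate_test_image("tissue", seed = 7)$pixels / 50 # arbitrary scale
  got <- stub_extractor(px, seed = 9, output_dim = 12)
  # oracle: block-mean downsample by plain loops, then the seeded projection
  side <- 32L; f <- 224L %/% side
  small <- array(0, c(side, side, 3))
  for (ch in 1:3) for (i in seq_len(side)) for (j in seq_len(side)) {
    small[i, j, ch] <- mean(px[(i - 1) * f + 1:f, (j - 1) * f + 1:f, ch])
  }
  flat <- as.vector(small)
  proj <- withr::with_seed(9, matrix(rnorm(length(flat) * 12),
                                     nrow = length(flat)) / sqrt(length(flat)))
  expect_equal(got, tanh(drop(crossprod(proj, flat))), tolerance = 1e-12)
})

test_that("stub extractor is deterministic, seed-sensitive, and maps zero to zero", {
  px <- simulate_test_image("blood", seed = 1)$pixels
  expect_identical(stub_extractor(px, seed = 3, output_dim = 16),
                   stub_extractor(px, seed = 3, output_dim = 16))
  expect_false(identical(stub_extractor(px, seed = 3, output_dim = 16),
                         stub_extractor(px, seed = 4, output_dim = 16)))
  expect_equal(stub_extractor(array(0, c(224, 224, 3)), seed = 3, output_dim = 16),
               rep(0, 16))
})

test_that("extraction applies channel normalization and defaults to 2048 dimensions", {
  patches <- list(simulate_test_image("tissue", seed = 2)$pixels,
                  simulate_test_image("tissue", seed = 2)$pixels)
  bag <- extract_features(patches, extractor_spec(seed = 1), slide_id = "s1")
  expect_equal(ncol(bag$features), 2048)
  expect_identical(bag$features[1, ], bag$features[2, ]) # identical patches
  # normalization: a patch equal to the channel means maps to the zero vector
  spec <- extractor_spec(output_dim = 8)
  mean_patch <- array(0, c(224, 224, 3))
  for (ch in 1:3) mean_patch[, , ch] <- spec$channel_means[ch] * 255
  bagm <- extract_features(list(mean_patch), spec, slide_id = "s2")
  expect_equal(unname(bagm$features[1, ]), rep(0, 8), tolerance = 1e-12)
})

test_that("the feature cache round-trips bit-identically and repeat calls hit it", {
  cache <- withr::local_tempdir()
  patches <- list(simulate_test_image("tissue", seed = 5)$pixels)
  spec <- extractor_spec(output_dim = 6, seed = 2)
  b1 <- extract_features(patches, spec, slide_id = "sA", cache_dir = cache)
  expect_length(list.files(cache), 1L)
  # second call must come from the cache even if patches differ
  b2 <- extract_features(list(simulate_test_image("blood", seed = 5)$pixels),
                         spec, slide_id = "sA", cache_dir = cache)
  expect_identical(b1$features, b2$features)
  f <- file.path(cache, "roundtrip.rds")
  write_feature_bag(b1, f)
  expect_identical(read_feature_bag(f)$features, b1$features)
})

test_that("the extractor stays frozen across estimator training", {
  proj_before <- milfc:::stub_projection(3072, 6, 2)
  co <- tiny_cohort(n = 10, seed = 9)
  suppressWarnings(train_fc_estimator(co$bags[1:6], co$labels[1:6, ], "1p",
                                      config = quick_train_config(max_epochs = 2L)))
  expect_identical(milfc:::stub_projection(3072, 6, 2), proj_before)
})

test_that("unregistered extractors are rejected", {
  expect_error(extract_features(list(array(0, c(224, 224, 3))),
                                extractor_spec(name = "nonexistent")),
               "not registered")
})

test_that("stub features of distinct fixture kinds are linearly separable across seeds", {
  hits <- 0L
  for (s in 1:20) {
    imgs <- c(lapply(1:6, function(i) simulate_test_image("tissue", seed = 100 * s + i)$pixels),
              lapply(1:6, function(i) simulate_test_image("blood", seed = 200 * s + i)$pixels))
    spec <- extractor_spec(output_dim = 8, seed = s)
    feats <- t(vapply(imgs, function(p) {
      stub_extractor(milfc:::normalize_patch(p, spec), seed = s, output_dim = 8)
    }, numeric(8)))
    y <- rep(c(0, 1), each = 6)
    # linear probe: least-squares hyperplane, training accuracy
    fit <- stats::lm.fit(cbind(1, feats), y)
    beta <- ifelse(is.na(fit$coefficients), 0, fit$coefficients)
    acc <- mean((cbind(1, feats) %*% beta > 0.5) == (y == 1))
    if (acc == 1) hits <- hits + 1L
  }
  expect_gte(hits, 19L)
})
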