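# shared fixtures, all generated in code

random_bag <- function(P = 50, D = 8, seed = 1) {
  withr::with_seed(seed, {
    feature_bag(sprintf("bag_s%d", seed),
                matrix(rnorm(P * D), nrow = P, ncol = D),
                milfc:::synthetic_coords(P),
                extractor_id = "test")
  })
}

random_fc_params <- function(D = 8, N = 3, seed = 1) {
  p <- fc_params_init(D, N, "1p", hidden = c(6L, 4L), seed = seed)
  # unit tests want a non-degenerate scorer
  p$scorer_w <- withr::with_seed(seed, rnorm(D))
  p
}

tiny_cohort <- function(n = 24, seed = 3) {
  simulate_cohort(n, n_patches_range = c(40L, 70L), feature_dim = 12L,
                  effect_size = 2.5, label_noise_sd = 0.01, seed = seed)
}

quick_train_config <- function(max_epochs = 10L, ...) {
  train_config(n_extreme = 8L, max_epochs = max_epochs, seed = 5L, ...)
}
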