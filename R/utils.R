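## shared internal helpers

sigmoid <- function(x) plogis(x)

`%||%` <- rlang::`%||%`

#' Derive a per-item seed from a master seed
#'
#' Deterministic multiplicative hash giving independent, reproducible RNG
#' streams for each slide (or replicate) of a cohort. Result is always a
#' positive integer below 2^31.
#'
#' @param master_seed Integer master seed.
#' @param index 1-based item index (may be a vector).
#' @return Integer vector of derived seeds.
#' @export
derive_seed <- function(master_seed, index) {
  stopifnot(is.numeric(master_seed), length(master_seed) == 1L, is.numeric(index))
  m <- 2147483647 # 2^31 - 1, Lehmer modulus
  s <- (abs(master_seed) %% m)
  out <- ((s * 48271) %% m + (index * 69621) %% m) %% m
  as.integer(out %% (m - 2) + 1)
}

stop_if_not_scalar_prob <- function(x, name) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x) || x < 0 || x > 1) {
    abort(sprintf("`%s` must be a single value in [0, 1], got %s", name,
                  paste(format(x), collapse = ", ")))
  }
  invisible(x)
}

assert_count <- function(x, name, min = 1L) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x) || x < min || x != round(x)) {
    abort(sprintf("`%s` must be a single integer >= %d", name, min))
  }
  invisible(as.integer(x))
}

assert_finite_matrix <- function(x, name) {
  if (!is.matrix(x) || !is.numeric(x) || anyNA(x) || any(!is.finite(x))) {
    abort(sprintf("`%s` must be a numeric matrix with no non-finite values", name))
  }
  invisible(x)
}
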