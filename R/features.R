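## Frozen feature extraction. Patches are scaled to [0,1], ImageNet
## channel-normalized, and passed through a registered extractor. A real
## pretrained histopathology encoder can be plugged in via
## register_extractor(); the package ships a deterministic stub (seeded
## random projection of the downsampled patch + tanh) so the full pipeline
## runs without pretrained weights.

the_extractors <- new.env(parent = emptyenv())

#' Register a pluggable feature extractor
#'
#' An extractor is a function `(normalized_patch_array, spec) -> numeric
#' vector` of length `spec$output_dim`. The built-in `"stub"` extractor is
#' pre-registered.
#'
#' @param name Extractor name.
#' @param fn Extractor function.
#' @export
register_extractor <- function(name, fn) {
  stopifnot(is.character(name), is.function(fn))
  assign(name, fn, envir = the_extractors)
  invisible(name)
}

#' Specification of a (frozen) feature extractor
#'
#' @param name Registered extractor name (`"stub"` by default).
#' @param output_dim Feature dimension D (default 2048, the penultimate
#'   layer width of typical pretrained histopathology encoders).
#' @param channel_means,channel_sds Per-channel normalization applied to
#'   pixel values scaled to \[0, 1\] before extraction (ImageNet constants
#'   by default).
#' @param seed Seed of the stub's random projection.
#' @return A list of class `extractor_spec`; `frozen` is always `TRUE`.
#' @export
extractor_spec <- function(name = "stub", output_dim = 2048L,
                           channel_means = c(0.485, 0.456, 0.406),
                           channel_sds = c(0.229, 0.224, 0.225),
                           seed = 1L) {
  if (output_dim < 2) abort("`output_dim` must be >= 2")
  structure(list(name = name, output_dim = as.integer(output_dim),
                 channel_means = channel_means, channel_sds = channel_sds,
                 seed = as.integer(seed), frozen = TRUE),
            class = "extractor_spec")
}

extractor_id <- function(spec) {
  sprintf("%s-d%d-s%d", spec$name, spec$output_dim, spec$seed)
}

## ImageNet-style normalization of a 0-255 patch
normalize_patch <- function(px, spec) {
  px <- as_pixels(px) / 255
  for (ch in 1:3) {
    px[, , ch] <- (px[, , ch] - spec$channel_means[ch]) / spec$channel_sds[ch]
  }
  px
}

## memoized seeded Gaussian projection matrices
the_projections <- new.env(parent = emptyenv())

stub_projection <- function(in_dim, out_dim, seed) {
  key <- sprintf("%d_%d_%d", in_dim, out_dim, seed)
  if (!is.null(the_projections[[key]])) return(the_projections[[key]])
  proj <- withr::with_seed(seed, {
    matrix(rnorm(in_dim * out_dim), nrow = in_dim) / sqrt(in_dim)
  })
  the_projections[[key]] <- proj
  proj
}

#' Deterministic stub feature extractor
#'
#' Downsamples the (already channel-normalized) patch to 32 x 32 by block
#' averaging, flattens it, applies a fixed seed-generated Gaussian random
#' projection to `output_dim` dimensions, and squashes elementwise with
#' tanh. Deterministic in (patch, seed); a zero input maps to the zero
#' vector.
#'
#' @param patch Normalized H x W x 3 numeric array (see
#'   [extract_features()] for the normalization).
#' @param seed Projection seed.
#' @param output_dim Output dimension D.
#' @return Numeric vector of length `output_dim`.
#' @export
stub_extractor <- function(patch, seed = 1L, output_dim = 2048L) {
  px <- as_pixels(patch)
  side <- 32L
  f <- floor(min(dim(px)[1:2]) / side)
  if (f < 1L) abort("patch smaller than the 32 x 32 stub input")
  small <- vapply(1:3, function(ch) {
    block_mean(px[seq_len(side * f), seq_len(side * f), ch], f)
  }, matrix(0, side, side))
  flat <- as.vector(small)
  proj <- stub_projection(length(flat), output_dim, seed)
  tanh(drop(crossprod(proj, flat)))
}

register_extractor("stub", function(patch, spec) {
  stub_extractor(patch, seed = spec$seed, output_dim = spec$output_dim)
})

#' Extract per-patch feature vectors for one slide
#'
#' Scales each patch to \[0, 1\], applies the spec's channel normalization,
#' and runs the registered extractor. When `cache_dir` is given, the
#' resulting bag is written to disk keyed by (slide id, extractor id) and
#' repeat calls return the cached matrix bit-identically.
#'
#' @param patches List of patch pixel arrays (0-255), all the same size.
#' @param spec An [extractor_spec()].
#' @param slide_id Slide identifier.
#' @param coords Optional coordinate tibble aligned with `patches`
#'   (defaults to a synthetic square grid).
#' @param cache_dir Optional directory for the on-disk feature cache.
#' @return A [feature_bag()].
#' @export
extract_features <- function(patches, spec = extractor_spec(), slide_id = "slide_1",
                             coords = NULL, cache_dir = NULL) {
  if (length(patches) < 1L) abort("no patches to extract")
  if (!exists(spec$name, envir = the_extractors)) {
    abort(sprintf("extractor '%s' is not registered", spec$name))
  }
  eid <- extractor_id(spec)
  cache_file <- if (!is.null(cache_dir)) {
    dir.create(cache_dir, showWarnings = FALSE, recursive = TRUE)
    file.path(cache_dir, sprintf("%s_%s.rds", slide_id, eid))
  }
  if (!is.null(cache_file) && file.exists(cache_file)) {
    return(readRDS(cache_file))
  }
  fn <- get(spec$name, envir = the_extractors)
  feats <- t(vapply(patches, function(p) {
    v <- fn(normalize_patch(p, spec), spec)
    if (anyNA(v) || any(!is.finite(v))) {
      abort("extractor produced non-finite features for a patch")
    }
    v
  }, numeric(spec$output_dim)))
  bag <- feature_bag(slide_id, feats,
                     coords %||% synthetic_coords(length(patches)),
                     extractor_id = eid, normalization_id = "imagenet")
  if (!is.null(cache_file)) saveRDS(bag, cache_file)
  bag
}

#' Read and write feature bags
#'
#' One keyed container per slide holding the feature matrix and the patch
#' coordinate table.
#'
#' @param bag A [feature_bag()].
#' @param path File path (`.rds`).
#' @return `read_feature_bag()` returns the bag; `write_feature_bag()`
#'   returns `path` invisibly.
#' @export
write_feature_bag <- function(bag, path) {
  stopifnot(inherits(bag, "feature_bag"))
  saveRDS(bag, path)
  invisible(path)
}

#' @rdname write_feature_bag
#' @export
read_feature_bag <- function(path) {
  bag <- readRDS(path)
  if (!inherits(bag, "feature_bag")) abort("file does not contain a feature_bag")
  bag
}
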