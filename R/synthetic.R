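## Synthetic fixtures: feature bags with planted copy-number signal, and
## small RGB test images for the patch filters. These emulate the study
## conditions (FC standardized to 1 in normal tissue, dropping to 1 - 0.5*t
## for a hemizygously deleted arm at tumor purity t, i.e. 0.5-0.8 over
## purities 0.4-1.0) so every downstream module is testable without slides.

#' Specification of one synthetic slide
#'
#' A generative recipe for a feature bag with known ground truth. A fraction
#' `tumor_purity` of the patches are "tumor" patches; when a chromosome arm
#' is deleted, their feature mean is shifted by
#' `effect_size * feature_noise_sd` along a fixed arm-specific signal
#' direction (axis 1 for 1p, axis 2 for 19q, so the two arms are
#' orthogonal and separable). The slide-level FC label for an arm is
#' `1 - 0.5 * tumor_purity` if the arm is deleted and `1.0` otherwise
#' (one of two alleles lost in tumor cells), plus optional Gaussian label
#' noise, clipped to (0, 1.5].
#'
#' @param n_patches Number of patches in the bag (>= 1).
#' @param tumor_purity Fraction of tumor patches, in \[0, 1\].
#' @param deleted_1p,deleted_19q Logical deletion status per arm.
#' @param feature_dim Feature dimension D (>= 2).
#' @param effect_size Separation of the deleted-tumor patch mean from the
#'   background mean, in units of `feature_noise_sd`.
#' @param feature_noise_sd Isotropic feature noise SD (> 0).
#' @param label_noise_sd SD of Gaussian noise added to the slide FC label.
#' @param seed Integer seed; generation is bit-identical for identical
#'   spec + seed.
#' @return An object of class `slide_spec`.
#' @export
slide_spec <- function(n_patches, tumor_purity, deleted_1p, deleted_19q,
                       feature_dim = 64L, effect_size = 2, feature_noise_sd = 1,
                       label_noise_sd = 0, seed = 1L) {
  assert_count(n_patches, "n_patches")
  stop_if_not_scalar_prob(tumor_purity, "tumor_purity")
  stopifnot(is.logical(deleted_1p), length(deleted_1p) == 1L,
            is.logical(deleted_19q), length(deleted_19q) == 1L)
  if (!is.numeric(feature_dim) || feature_dim < 2) {
    abort("`feature_dim` must be >= 2")
  }
  if (!is.numeric(effect_size) || effect_size < 0) abort("`effect_size` must be >= 0")
  if (!is.numeric(feature_noise_sd) || feature_noise_sd <= 0) {
    abort("`feature_noise_sd` must be > 0")
  }
  if (!is.numeric(label_noise_sd) || label_noise_sd < 0) {
    abort("`label_noise_sd` must be >= 0")
  }
  structure(
    list(n_patches = as.integer(n_patches), tumor_purity = tumor_purity,
         deleted_1p = deleted_1p, deleted_19q = deleted_19q,
         feature_dim = as.integer(feature_dim), effect_size = effect_size,
         feature_noise_sd = feature_noise_sd, label_noise_sd = label_noise_sd,
         seed = as.integer(seed)),
    class = "slide_spec"
  )
}

#' Construct a feature bag
#'
#' Container for one slide: a P x D matrix of per-patch feature vectors and
#' the patch grid coordinates its rows align with.
#'
#' @param slide_id Slide identifier.
#' @param features Numeric P x D matrix, no non-finite values.
#' @param coords Tibble with one row per patch (columns `patch_id`, `row`,
#'   `col`, `x0`, `y0`), aligned 1:1 with `features` rows.
#' @param extractor_id,normalization_id Provenance strings.
#' @return An object of class `feature_bag`.
#' @export
feature_bag <- function(slide_id, features, coords,
                        extractor_id = "unknown", normalization_id = "none") {
  assert_finite_matrix(features, "features")
  if (nrow(features) < 1L) abort("a feature bag needs at least one patch")
  if (!is.data.frame(coords) || nrow(coords) != nrow(features)) {
    abort("`coords` must have one row per feature row")
  }
  structure(
    list(slide_id = as.character(slide_id), features = features,
         coords = tibble::as_tibble(coords),
         extractor_id = extractor_id, normalization_id = normalization_id),
    class = "feature_bag"
  )
}

#' @export
print.feature_bag <- function(x, ...) {
  cat(sprintf("<feature_bag> slide '%s': %d patches x %d features (extractor: %s)\n",
              x$slide_id, nrow(x$features), ncol(x$features), x$extractor_id))
  invisible(x)
}

## square-ish grid coordinates for P synthetic patches
synthetic_coords <- function(n_patches, patch_size = 224L) {
  ncol_grid <- ceiling(sqrt(n_patches))
  idx <- seq_len(n_patches) - 1L
  row <- idx %/% ncol_grid
  col <- idx %% ncol_grid
  tibble::tibble(patch_id = seq_len(n_patches), row = as.integer(row),
                 col = as.integer(col),
                 x0 = as.integer(col * patch_size), y0 = as.integer(row * patch_size))
}

#' Simulate one slide as a feature bag with ground truth
#'
#' Draws background patches from an isotropic Gaussian and tumor patches
#' from the same Gaussian with the deletion mean-shift described in
#' [slide_spec()]. Deterministic: identical spec (including seed) gives
#' bit-identical output.
#'
#' @param spec A [slide_spec()].
#' @param slide_id Identifier for the resulting bag.
#' @return A list with elements `bag` (a [feature_bag()]) and `truth`, a
#'   one-row tibble with columns `slide_id`, `fc_1p`, `fc_19q`,
#'   `tumor_type`, `tumor_purity`, and a list-column `tumor_patches`
#'   holding the planted tumor patch indices.
#' @export
simulate_slide <- function(spec, slide_id = "slide_1") {
  if (!inherits(spec, "slide_spec")) abort("`spec` must be a slide_spec")
  P <- spec$n_patches
  D <- spec$feature_dim
  t <- spec$tumor_purity
  withr::with_seed(spec$seed, {
    feat <- matrix(rnorm(P * D, sd = spec$feature_noise_sd), nrow = P, ncol = D)
    n_tumor <- round(t * P)
    tumor_idx <- if (n_tumor > 0) sort(sample.int(P, n_tumor)) else integer(0)
    shift <- spec$effect_size * spec$feature_noise_sd
    if (spec$deleted_1p && n_tumor > 0) {
      feat[tumor_idx, 1L] <- feat[tumor_idx, 1L] + shift
    }
    if (spec$deleted_19q && n_tumor > 0) {
      feat[tumor_idx, 2L] <- feat[tumor_idx, 2L] + shift
    }
    fc_clean <- function(deleted) if (deleted) 1 - 0.5 * t else 1.0
    noise <- rnorm(2L, sd = spec$label_noise_sd)
    fc_1p <- min(max(fc_clean(spec$deleted_1p) + noise[1L], 1e-6), 1.5)
    fc_19q <- min(max(fc_clean(spec$deleted_19q) + noise[2L], 1e-6), 1.5)
  })
  type <- if (spec$deleted_1p && spec$deleted_19q) "oligodendroglioma" else "astrocytoma"
  bag <- feature_bag(slide_id, feat, synthetic_coords(P),
                     extractor_id = "synthetic", normalization_id = "none")
  truth <- tibble::tibble(
    slide_id = as.character(slide_id), fc_1p = fc_1p, fc_19q = fc_19q,
    tumor_type = type, tumor_purity = t,
    deleted_1p = spec$deleted_1p, deleted_19q = spec$deleted_19q,
    tumor_patches = list(tumor_idx)
  )
  list(bag = bag, truth = truth)
}

#' Simulate a cohort of slides
#'
#' Generates `n_slides` bags with tumor types balanced to within one slide
#' (oligodendroglioma = both arms deleted, astrocytoma = both intact),
#' purities drawn uniformly from `purity_range`, and bag sizes uniformly
#' from `n_patches_range`. Per-slide seeds are derived deterministically
#' from the master seed so the cohort is reproducible bit-identically.
#'
#' @param n_slides Number of slides (>= 1).
#' @param purity_range Length-2 range for tumor purity, within \[0, 1\].
#' @param n_patches_range Length-2 integer range for patches per slide.
#' @inheritParams slide_spec
#' @param seed Master seed.
#' @return A list of class `slide_cohort`: `bags` (named list of
#'   [feature_bag()]s) and `labels` (tibble, one row per slide, with the
#'   same columns as the `truth` of [simulate_slide()]).
#' @export
simulate_cohort <- function(n_slides, purity_range = c(0.4, 1.0),
                            n_patches_range = c(200L, 600L),
                            feature_dim = 64L, effect_size = 2,
                            feature_noise_sd = 1, label_noise_sd = 0.02,
                            seed = 1L) {
  assert_count(n_slides, "n_slides")
  if (length(purity_range) != 2L || purity_range[1] > purity_range[2] ||
      purity_range[1] < 0 || purity_range[2] > 1) {
    abort("`purity_range` must be an ordered range within [0, 1]")
  }
  if (length(n_patches_range) != 2L || n_patches_range[1] > n_patches_range[2] ||
      n_patches_range[1] < 1) {
    abort("`n_patches_range` must be an ordered positive range")
  }
  n_oligo <- ceiling(n_slides / 2)
  is_oligo <- rep(c(TRUE, FALSE), length.out = n_slides)
  withr::with_seed(derive_seed(seed, 0L), {
    purities <- runif(n_slides, purity_range[1], purity_range[2])
    sizes <- if (n_patches_range[1] == n_patches_range[2]) {
      rep(n_patches_range[1], n_slides)
    } else {
      sample(seq(n_patches_range[1], n_patches_range[2]), n_slides, replace = TRUE)
    }
  })
  sims <- purrr::map(seq_len(n_slides), function(i) {
    sp <- slide_spec(
      n_patches = sizes[i], tumor_purity = purities[i],
      deleted_1p = is_oligo[i], deleted_19q = is_oligo[i],
      feature_dim = feature_dim, effect_size = effect_size,
      feature_noise_sd = feature_noise_sd, label_noise_sd = label_noise_sd,
      seed = derive_seed(seed, i)
    )
    simulate_slide(sp, slide_id = sprintf("slide_%03d", i))
  })
  bags <- purrr::map(sims, "bag")
  names(bags) <- purrr::map_chr(bags, "slide_id")
  labels <- purrr::list_rbind(purrr::map(sims, "truth"))
  structure(list(bags = bags, labels = labels), class = "slide_cohort")
}

#' @export
print.slide_cohort <- function(x, ...) {
  cat(sprintf("<slide_cohort> %d slides (%d oligodendroglioma, %d astrocytoma)\n",
              nrow(x$labels), sum(x$labels$tumor_type == "oligodendroglioma"),
              sum(x$labels$tumor_type == "astrocytoma")))
  invisible(x)
}

## vectorized HSV (h,s,v in [0,1]) -> RGB in [0,255]
hsv_to_rgb255 <- function(h, s, v) {
  h6 <- (h %% 1) * 6
  i <- floor(h6)
  f <- h6 - i
  p <- v * (1 - s)
  q <- v * (1 - f * s)
  t <- v * (1 - (1 - f) * s)
  r <- g <- b <- numeric(length(h))
  sel <- function(k) i == k
  r[sel(0)] <- v[sel(0)]; g[sel(0)] <- t[sel(0)]; b[sel(0)] <- p[sel(0)]
  r[sel(1)] <- q[sel(1)]; g[sel(1)] <- v[sel(1)]; b[sel(1)] <- p[sel(1)]
  r[sel(2)] <- p[sel(2)]; g[sel(2)] <- v[sel(2)]; b[sel(2)] <- t[sel(2)]
  r[sel(3)] <- p[sel(3)]; g[sel(3)] <- q[sel(3)]; b[sel(3)] <- v[sel(3)]
  r[sel(4)] <- t[sel(4)]; g[sel(4)] <- p[sel(4)]; b[sel(4)] <- v[sel(4)]
  r[sel(5)] <- v[sel(5)]; g[sel(5)] <- q[sel(5)]; b[sel(5)] <- p[sel(5)]
  cbind(r, g, b) * 255
}

## piecewise-constant random texture: random level per `block`-pixel cell
block_texture <- function(size, block, lo, hi) {
  nb <- ceiling(size / block)
  levels <- matrix(runif(nb * nb, lo, hi), nb, nb)
  up <- kronecker(levels, matrix(1, block, block))
  as.vector(up[seq_len(size), seq_len(size)])
}

#' Construct an RGB image
#'
#' @param pixels H x W x 3 numeric array of intensities in \[0, 255\]
#'   (channel order red, green, blue).
#' @param microns_per_pixel Physical resolution, or `NA` if unknown.
#' @return An object of class `rgb_image`.
#' @export
rgb_image <- function(pixels, microns_per_pixel = NA_real_) {
  if (!is.array(pixels) || length(dim(pixels)) != 3L || dim(pixels)[3] != 3L) {
    abort("`pixels` must be an H x W x 3 array")
  }
  structure(list(pixels = pixels, microns_per_pixel = microns_per_pixel),
            class = "rgb_image")
}

#' @export
print.rgb_image <- function(x, ...) {
  d <- dim(x$pixels)
  cat(sprintf("<rgb_image> %d x %d pixels (%s um/px)\n", d[1], d[2],
              ifelse(is.na(x$microns_per_pixel), "unknown",
                     format(x$microns_per_pixel))))
  invisible(x)
}

#' Generate a synthetic test image for the patch filters
#'
#' Three fixture kinds mimicking what the background and blood filters must
#' separate: `tissue` is a high-frequency texture in H&E-like purple hues,
#' `background` is a near-uniform bright field, and `blood` is a textured
#' saturated red field. Deterministic in `seed`.
#'
#' @param kind One of `"tissue"`, `"background"`, `"blood"`.
#' @param size Image side in pixels (>= 224).
#' @param seed Integer seed.
#' @return An [rgb_image()] of dimension `size` x `size` x 3.
#' @export
simulate_test_image <- function(kind = c("tissue", "background", "blood"),
                                size = 224L, seed = 1L) {
  kind <- rlang::arg_match(kind)
  if (!is.numeric(size) || size < 224) abort("`size` must be >= 224")
  size <- as.integer(size)
  n <- size * size
  px <- withr::with_seed(seed, {
    switch(kind,
      background = {
        base <- c(247, 245, 248)
        arr <- array(0, dim = c(size, size, 3L))
        for (ch in 1:3) arr[, , ch] <- base[ch] + rnorm(n, sd = 0.6)
        arr
      },
      tissue = {
        # hues 245-300 deg: hematoxylin purple through eosin violet-pink;
        # nucleus-scale blocky value texture so patches carry strong edges
        h <- runif(n, 245 / 360, 300 / 360)
        s <- runif(n, 0.30, 0.70)
        v <- pmin(pmax(block_texture(size, 14L, 0.45, 0.95) +
                         rnorm(n, sd = 0.02), 0), 1)
        rgb <- hsv_to_rgb255(h, s, v)
        array(rgb, dim = c(size, size, 3L))
      },
      blood = {
        # saturated red: hue < 10 on the 0-179 scale, with blocky value
        # texture so the patch carries edges (blood is discarded by color,
        # not by the background rule)
        h <- runif(n, 0, 9 / 360)
        s <- runif(n, 0.55, 0.95)
        v <- pmin(pmax(block_texture(size, 14L, 0.35, 0.90) +
                         rnorm(n, sd = 0.02), 0), 1)
        rgb <- hsv_to_rgb255(h, s, v)
        array(rgb, dim = c(size, size, 3L))
      }
    )
  })
  px <- pmin(pmax(px, 0), 255)
  rgb_image(px, microns_per_pixel = 0.5) # 20x-equivalent
}
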