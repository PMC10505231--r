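## Slide preparation: tile into non-overlapping 224x224 patches at a
## 20x-equivalent scale, discard textureless background (edge-pixel count
## below a threshold) and blood-colored patches (HSV bounds), and optionally
## match external slides to a reference color distribution.

#' Filter configuration for background and blood detection
#'
#' A background patch is one whose Canny edge-pixel count is strictly below
#' `edge_count_threshold`. A blood patch is one where at least
#' `blood_pixel_fraction` of pixels fall inside the HSV blood bounds (hue on
#' the 0-179 scale with the red wrap-around covered by two intervals;
#' saturation and value on the 0-255 scale).
#'
#' @param edge_count_threshold Strict upper bound on edge pixels for
#'   background (default 23).
#' @param canny_low,canny_high Hysteresis thresholds of the Canny detector
#'   on the 8-bit gradient-magnitude scale.
#' @param blood_hue_bounds 2 x 2 matrix of `[low, high]` hue intervals on
#'   the 0-179 scale (rows), covering the red wrap-around.
#' @param blood_saturation_min,blood_value_min Minimum saturation / value
#'   (0-255 scale).
#' @param blood_pixel_fraction Minimum in-bounds pixel fraction to call a
#'   patch blood.
#' @return A list of class `filter_config`.
#' @export
filter_config <- function(edge_count_threshold = 23L,
                          canny_low = 50, canny_high = 150,
                          blood_hue_bounds = rbind(c(0, 10), c(160, 179)),
                          blood_saturation_min = 100,
                          blood_value_min = 60,
                          blood_pixel_fraction = 0.5) {
  stopifnot(edge_count_threshold >= 0, canny_low <= canny_high,
            is.matrix(blood_hue_bounds), ncol(blood_hue_bounds) == 2L,
            all(blood_hue_bounds[, 1] <= blood_hue_bounds[, 2]),
            blood_pixel_fraction > 0, blood_pixel_fraction <= 1)
  structure(list(edge_count_threshold = as.integer(edge_count_threshold),
                 canny_low = canny_low, canny_high = canny_high,
                 blood_hue_bounds = blood_hue_bounds,
                 blood_saturation_min = blood_saturation_min,
                 blood_value_min = blood_value_min,
                 blood_pixel_fraction = blood_pixel_fraction),
            class = "filter_config")
}

as_pixels <- function(image) {
  if (inherits(image, "rgb_image")) image$pixels
  else if (is.array(image) && length(dim(image)) == 3L) image
  else abort("expected an rgb_image or an H x W x 3 array")
}

## 2x2 (or f x f) block-mean downsampling of one channel
block_mean <- function(mat, f) {
  h <- floor(nrow(mat) / f) * f
  w <- floor(ncol(mat) / f) * f
  m <- mat[seq_len(h), seq_len(w), drop = FALSE]
  # average rows then columns within blocks
  m <- (matrix(m, nrow = f) |> colMeans()) |> matrix(nrow = h / f)
  t(matrix(colMeans(matrix(t(m), nrow = f)), nrow = w / f))
}

#' Tile a slide into non-overlapping patches at 20x
#'
#' Downsamples the image to a 20x-equivalent resolution (40x scans are
#' block-averaged by a factor of 2), then cuts the full grid of
#' `floor(H/patch_size) x floor(W/patch_size)` patches; remainder strips
#' smaller than one patch are dropped. Pixel origin is the image's top-left
#' corner and offsets refer to the 20x image.
#'
#' @param image An [rgb_image()].
#' @param patch_size Patch side in pixels (default 224).
#' @param magnification Native objective power of `image` (20 or 40).
#' @return A list of class `patch_grid_set`: `grid`, a tibble with columns
#'   `patch_id`, `row`, `col`, `x0`, `y0`, `status` (all `"kept"`), and
#'   `patches`, a list of patch pixel arrays aligned with `grid` rows.
#' @export
tile_slide <- function(image, patch_size = 224L, magnification = c(20, 40)) {
  px <- as_pixels(image)
  if (is.character(magnification)) magnification <- as.numeric(magnification)
  if (length(magnification) > 1L) {
    abort("`magnification` of the scan must be given (20 or 40); none recorded on the image")
  }
  if (!magnification %in% c(20, 40)) abort("`magnification` must be 20 or 40")
  if (magnification == 40) {
    f <- 2L
    px <- simplify2array(lapply(1:3, function(ch) block_mean(px[, , ch], f)))
  }
  H <- dim(px)[1]; W <- dim(px)[2]
  nr <- floor(H / patch_size); nc <- floor(W / patch_size)
  if (nr < 1L || nc < 1L) {
    abort(sprintf("image (%d x %d at 20x) is smaller than one %d-pixel patch",
                  H, W, patch_size))
  }
  grid <- tidyr::expand_grid(row = seq_len(nr) - 1L, col = seq_len(nc) - 1L)
  grid <- dplyr::mutate(grid,
                        patch_id = dplyr::row_number(),
                        x0 = .data$col * as.integer(patch_size),
                        y0 = .data$row * as.integer(patch_size),
                        status = "kept")
  grid <- dplyr::select(grid, "patch_id", "row", "col", "x0", "y0", "status")
  patches <- purrr::pmap(grid[, c("x0", "y0")], function(x0, y0) {
    px[y0 + seq_len(patch_size), x0 + seq_len(patch_size), , drop = FALSE]
  })
  structure(list(grid = grid, patches = patches, patch_size = as.integer(patch_size)),
            class = "patch_grid_set")
}

#' @export
print.patch_grid_set <- function(x, ...) {
  cat(sprintf("<patch_grid_set> %d patches of %d px (%s)\n", nrow(x$grid),
              x$patch_size,
              paste(names(table(x$grid$status)), table(x$grid$status),
                    sep = ": ", collapse = ", ")))
  invisible(x)
}

shift_mat <- function(m, dr, dc, fill = 0) {
  H <- nrow(m); W <- ncol(m)
  out <- matrix(fill, H, W)
  rs <- max(1, 1 + dr):min(H, H + dr)
  cs <- max(1, 1 + dc):min(W, W + dc)
  out[rs, cs] <- m[rs - dr, cs - dc]
  out
}

## replicate-padded 2D convolution with a small kernel
conv2_rep <- function(m, k) {
  kr <- (nrow(k) - 1L) %/% 2L
  kc <- (ncol(k) - 1L) %/% 2L
  H <- nrow(m); W <- ncol(m)
  pad <- matrix(0, H + 2 * kr, W + 2 * kc)
  pad[kr + seq_len(H), kc + seq_len(W)] <- m
  if (kr > 0) {
    for (i in seq_len(kr)) {
      pad[i, kc + seq_len(W)] <- m[1, ]
      pad[H + kr + i, kc + seq_len(W)] <- m[H, ]
    }
  }
  if (kc > 0) {
    for (j in seq_len(kc)) {
      pad[, j] <- pad[, kc + 1]
      pad[, W + kc + j] <- pad[, W + kc]
    }
  }
  out <- matrix(0, H, W)
  for (i in seq_len(nrow(k))) {
    for (j in seq_len(ncol(k))) {
      if (k[i, j] != 0) {
        out <- out + k[i, j] * pad[(i - 1) + seq_len(H), (j - 1) + seq_len(W)]
      }
    }
  }
  out
}

#' Count edge pixels in a patch (Canny detector)
#'
#' Standard Canny on the grayscale patch: Gaussian smoothing (sigma 1),
#' Sobel gradients, non-maximum suppression along the quantized gradient
#' direction, then double-threshold hysteresis with the configured low/high
#' thresholds. Deterministic.
#'
#' @param patch An [rgb_image()] or pixel array (values 0-255).
#' @param low,high Hysteresis thresholds on the gradient-magnitude scale.
#' @return Integer count of edge pixels.
#' @export
count_edge_pixels <- function(patch, low = 50, high = 150) {
  px <- as_pixels(patch)
  if (dim(px)[1] < 8L || dim(px)[2] < 8L) abort("patch too small for edge detection")
  gray <- 0.299 * px[, , 1] + 0.587 * px[, , 2] + 0.114 * px[, , 3]
  g <- stats::dnorm(-2:2, sd = 1)
  g <- g / sum(g)
  smooth <- conv2_rep(conv2_rep(gray, matrix(g, nrow = 1)), matrix(g, ncol = 1))
  kx <- rbind(c(-1, 0, 1), c(-2, 0, 2), c(-1, 0, 1))
  gx <- conv2_rep(smooth, kx)       # horizontal (column) gradient
  gy <- conv2_rep(smooth, t(kx))    # vertical (row) gradient
  mag <- sqrt(gx^2 + gy^2)
  ang <- atan2(gy, gx) * 180 / pi
  ang[ang < 0] <- ang[ang < 0] + 180
  sector <- ifelse(ang < 22.5 | ang >= 157.5, 0L,
                   ifelse(ang < 67.5, 45L, ifelse(ang < 112.5, 90L, 135L)))
  neigh <- function(dr, dc) shift_mat(mag, dr, dc, fill = 0)
  n1 <- matrix(0, nrow(mag), ncol(mag)); n2 <- n1
  # compare along gradient direction (0: horizontal gradient -> left/right)
  for (s in c(0L, 45L, 90L, 135L)) {
    d <- switch(as.character(s),
                "0" = list(c(0, 1), c(0, -1)),
                "45" = list(c(-1, 1), c(1, -1)),
                "90" = list(c(1, 0), c(-1, 0)),
                "135" = list(c(-1, -1), c(1, 1)))
    m <- sector == s
    a <- neigh(d[[1]][1], d[[1]][2]); b <- neigh(d[[2]][1], d[[2]][2])
    n1[m] <- a[m]; n2[m] <- b[m]
  }
  nms <- mag > n1 & mag >= n2 # asymmetric tie rule keeps plateau edges 1 px wide
  strong <- nms & mag >= high
  weak <- nms & mag >= low & mag < high
  # hysteresis: grow strong edges through 8-connected weak pixels
  repeat {
    grown <- strong
    for (dr in -1:1) for (dc in -1:1) {
      if (dr == 0 && dc == 0) next
      grown <- grown | (weak & shift_mat(strong, dr, dc, fill = FALSE) > 0)
    }
    if (identical(grown, strong)) break
    strong <- grown
  }
  as.integer(sum(strong))
}

#' Is a patch textureless background?
#'
#' `TRUE` iff the Canny edge-pixel count is strictly below
#' `config$edge_count_threshold` (default 23).
#'
#' @param patch An [rgb_image()] or pixel array.
#' @param config A [filter_config()].
#' @return Logical.
#' @export
is_background <- function(patch, config = filter_config()) {
  count_edge_pixels(patch, config$canny_low, config$canny_high) <
    config$edge_count_threshold
}

#' Is a patch dominated by blood staining?
#'
#' Converts the patch to HSV (hue 0-179, saturation/value 0-255) and tests
#' whether the fraction of pixels inside the configured blood bounds is at
#' least `config$blood_pixel_fraction`.
#'
#' @inheritParams is_background
#' @return Logical.
#' @export
is_blood <- function(patch, config = filter_config()) {
  px <- as_pixels(patch)
  n <- prod(dim(px)[1:2])
  rgbm <- rbind(as.vector(px[, , 1]), as.vector(px[, , 2]), as.vector(px[, , 3]))
  hsv <- grDevices::rgb2hsv(rgbm, maxColorValue = 255)
  hue <- hsv[1, ] * 180 # OpenCV-style 0-179 scale
  sat <- hsv[2, ] * 255
  val <- hsv[3, ] * 255
  in_hue <- rep(FALSE, n)
  for (i in seq_len(nrow(config$blood_hue_bounds))) {
    b <- config$blood_hue_bounds[i, ]
    in_hue <- in_hue | (hue >= b[1] & hue <= b[2])
  }
  frac <- mean(in_hue & sat >= config$blood_saturation_min &
                 val >= config$blood_value_min)
  frac >= config$blood_pixel_fraction
}

#' Assign kept/background/blood status to every patch of a grid
#'
#' Background is checked first; a patch failing both predicates stays
#' `"kept"`. Statuses are mutually exclusive and the three groups partition
#' the grid.
#'
#' @param tiles A `patch_grid_set` from [tile_slide()], or a list with
#'   `grid` and `patches`.
#' @param config A [filter_config()].
#' @param quiet Suppress the per-reason discard message.
#' @return The grid tibble with updated `status`; discard counts are
#'   attached as attribute `"counts"`.
#' @export
filter_patches <- function(tiles, config = filter_config(), quiet = FALSE) {
  grid <- tiles$grid
  patches <- tiles$patches
  if (nrow(grid) != length(patches)) abort("grid and patches are misaligned")
  status <- purrr::map_chr(patches, function(p) {
    if (is_background(p, config)) "background"
    else if (is_blood(p, config)) "blood"
    else "kept"
  })
  grid$status <- status
  counts <- c(kept = sum(status == "kept"),
              background = sum(status == "background"),
              blood = sum(status == "blood"))
  if (!quiet) {
    rlang::inform(sprintf("patches: %d kept, %d background, %d blood discarded",
                          counts["kept"], counts["background"], counts["blood"]))
  }
  attr(grid, "counts") <- counts
  grid
}

lab_stats <- function(px) {
  m <- cbind(as.vector(px[, , 1]), as.vector(px[, , 2]), as.vector(px[, , 3])) / 255
  lab <- grDevices::convertColor(m, from = "sRGB", to = "Lab")
  list(mean = colMeans(lab), sd = apply(lab, 2, sd))
}

#' Fit reference color statistics from a set of patches
#'
#' Pools per-channel CIELAB means and SDs over the supplied patches; the
#' result is the target distribution for [normalize_color()].
#'
#' @param patches List of [rgb_image()]s or pixel arrays (e.g. kept patches
#'   of reference-scanner slides).
#' @return An object of class `color_reference` with `mean` and `sd` per
#'   Lab channel.
#' @export
fit_color_reference <- function(patches) {
  if (length(patches) < 1L) abort("need at least one patch")
  px <- lapply(patches, as_pixels)
  flat <- do.call(rbind, lapply(px, function(p) {
    cbind(as.vector(p[, , 1]), as.vector(p[, , 2]), as.vector(p[, , 3])) / 255
  }))
  lab <- grDevices::convertColor(flat, from = "sRGB", to = "Lab")
  structure(list(mean = colMeans(lab), sd = apply(lab, 2, sd)),
            class = "color_reference")
}

#' Match a patch's color distribution to a reference
#'
#' Reinhard-style channel-statistics matching in CIELAB: each Lab channel is
#' centered and rescaled so its mean and SD equal the reference's, then the
#' result is converted back to sRGB. Idempotent (up to color-space
#' round-trip error, about 1e-3 per channel) when the patch already has the
#' reference statistics. A degenerate patch (near-zero variance in some
#' channel) is returned unchanged with a warning. Intended for slides from
#' a different scanner/stainer; reference-scanner slides should skip it.
#'
#' @param patch An [rgb_image()] or pixel array.
#' @param reference A [fit_color_reference()] object.
#' @return An [rgb_image()] with continuous intensities in \[0, 255\].
#' @export
normalize_color <- function(patch, reference) {
  if (!inherits(reference, "color_reference")) {
    abort("`reference` must come from fit_color_reference()")
  }
  px <- as_pixels(patch)
  d <- dim(px)
  m <- cbind(as.vector(px[, , 1]), as.vector(px[, , 2]), as.vector(px[, , 3])) / 255
  lab <- grDevices::convertColor(m, from = "sRGB", to = "Lab")
  mu <- colMeans(lab); s <- apply(lab, 2, sd)
  if (any(s < 1e-8)) {
    warn("degenerate patch (zero variance channel); returned unchanged")
    return(rgb_image(px, if (inherits(patch, "rgb_image")) patch$microns_per_pixel else NA_real_))
  }
  lab2 <- sweep(sweep(lab, 2, mu), 2, reference$sd / s, `*`)
  lab2 <- sweep(lab2, 2, reference$mean, `+`)
  out <- grDevices::convertColor(lab2, from = "Lab", to = "sRGB")
  out <- pmin(pmax(out, 0), 1) * 255
  rgb_image(array(out, dim = d),
            if (inherits(patch, "rgb_image")) patch$microns_per_pixel else NA_real_)
}
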