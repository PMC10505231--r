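# tiling, background/blood filters, color normalization

const_image <- function(h, w, rgb = c(100, 100, 100)) {
  px <- array(0, dim = c(h, w, 3))
  for (ch in 1:3) px[, , ch] <- rgb[ch]
  rgb_image(px)
}

test_that("tiling cuts the full floor grid and drops sub-patch remainders", {
  t1 <- tile_slide(const_image(448, 448), magnification = 20)
  expect_equal(nrow(t1$grid), 4)
  expect_setequal(paste(t1$grid$x0, t1$grid$y0),
                  c("0 0", "224 0", "0 224", "224 224"))
  expect_true(all(t1$grid$status == "kept"))
  # 500x500: 52-pixel remainder strips dropped
  t2 <- tile_slide(const_image(500, 500), magnification = 20)
  expect_equal(nrow(t2$grid), 4)
  # 896x896 scanned at 40x: downsampled by 2 -> 448 -> 4 patches
  t3 <- tile_slide(const_image(896, 896), magnification = 40)
  expect_equal(nrow(t3$grid), 4)
  expect_equal(dim(t3$patches[[1]]), c(224, 224, 3))
  # offsets are multiples of the patch size and (row, col) pairs unique
  expect_true(all(t1$grid$x0 %% 224 == 0 & t1$grid$y0 %% 224 == 0))
  expect_false(any(duplicated(t1$grid[, c("row", "col")])))
})

test_that("tiling rejects too-small images and unknown magnification", {
  expect_error(tile_slide(const_image(200, 300), magnification = 20), "smaller")
  expect_error(tile_slide(const_image(400, 400), magnification = 40), "smaller")
  expect_error(tile_slide(const_image(448, 448)), "magnification")
  expect_error(tile_slide(const_image(448, 448), magnification = 60), "20 or 40")
})

test_that("edge-pixel counting: none on uniform patches, one column per clean step edge", {
  expect_equal(count_edge_pixels(const_image(224, 224)), 0L)
  # vertical two-level split: one edge pixel per row
  half <- array(50, dim = c(224, 224, 3))
  half[, 113:224, ] <- 200
  expect_equal(count_edge_pixels(half), 224L)
  # horizontal split likewise (detector is isotropic across the two axes)
  expect_equal(count_edge_pixels(aperm(half, c(2, 1, 3))), 224L)
  expect_error(count_edge_pixels(const_image(4, 4)), "small")
})

test_that("background rule is strict less-than on the edge count", {
  half <- array(50, dim = c(224, 224, 3))
  half[, 113:224, ] <- 200 # 224 edge pixels
  expect_false(is_background(half, filter_config(edge_count_threshold = 224)))
  expect_true(is_background(half, filter_config(edge_count_threshold = 225)))
  expect_true(is_background(const_image(224, 224))) # 0 < 23
})

test_that("blood rule thresholds the in-bounds pixel fraction", {
  cfg <- filter_config()
  # zero-saturation gray fails any positive saturation minimum
  expect_false(is_blood(const_image(224, 224, c(128, 128, 128)), cfg))
  # ~40% blood-colored pixels at fraction threshold 0.5 -> not blood
  mix <- array(0, dim = c(224, 224, 3))
  mix[, , 1] <- 128; mix[, , 2] <- 128; mix[, , 3] <- 128
  mix[, 1:89, 1] <- 200; mix[, 1:89, 2] <- 20; mix[, 1:89, 3] <- 20
  frac <- 89 / 224
  expect_lt(frac, 0.5)
  expect_false(is_blood(mix, cfg))
  # 60% blood-colored -> blood
  mix[, 1:135, 1] <- 200; mix[, 1:135, 2] <- 20; mix[, 1:135, 3] <- 20
  expect_true(is_blood(mix, cfg))
})

test_that("filter statuses partition the grid with background checked first", {
  patches <- list(simulate_test_image("tissue", seed = 2)$pixels,
                  simulate_test_image("background", seed = 2)$pixels,
                  simulate_test_image("blood", seed = 2)$pixels)
  grid <- tibble::tibble(patch_id = 1:3, row = 0L, col = 0:2,
                         x0 = 224L * (0:2), y0 = 0L, status = "kept")
  out <- filter_patches(list(grid = grid, patches = patches), quiet = TRUE)
  expect_equal(out$status, c("kept", "background", "blood"))
  expect_equal(unname(attr(out, "counts")),
               c(1L, 1L, 1L))
  # all-tissue grid keeps everything
  allt <- filter_patches(list(grid = grid,
                              patches = replicate(3, patches[[1]], simplify = FALSE)),
                         quiet = TRUE)
  expect_true(all(allt$status == "kept"))
  # empty grid passes through without error
  empty <- filter_patches(list(grid = grid[0, ], patches = list()), quiet = TRUE)
  expect_equal(nrow(empty), 0)
})

test_that("color normalization matches reference Lab statistics and is a fixed point", {
  ref_img <- simulate_test_image("tissue", seed = 31)
  other <- simulate_test_image("tissue", seed = 32)
  ref <- fit_color_reference(list(ref_img))
  out <- normalize_color(other, ref)
  # recompute stats on the output: matched up to color-space round-trip error
  got <- milfc:::lab_stats(out$pixels)
  expect_equal(got$mean, unname(ref$mean), tolerance = 1e-3, ignore_attr = TRUE)
  expect_equal(got$sd, unname(ref$sd), tolerance = 1e-3, ignore_attr = TRUE)
  # normalizing the reference against itself leaves it unchanged
  self <- normalize_color(ref_img, ref)
  expect_lt(max(abs(self$pixels - ref_img$pixels)), 0.05)
  # shape preserved
  expect_equal(dim(out$pixels), dim(other$pixels))
  # degenerate (uniform) patch returns unchanged with a warning
  u <- const_image(224, 224)
  expect_warning(keep <- normalize_color(u, ref), "degenerate")
  expect_identical(keep$pixels, u$pixels)
})
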