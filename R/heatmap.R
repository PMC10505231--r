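## Interpretability output: per-patch FC values painted over the slide grid
## (red = 1p/19q loss, blue = intact, purple = omitted background/blood
## patches) and the location table of the most extreme representative
## patches.

HEAT_RED <- c(220, 20, 20)     # fc = 0, loss
HEAT_BLUE <- c(20, 20, 220)    # fc = 1, intact
HEAT_PURPLE <- c(128, 0, 128)  # omitted cells

#' Map raw patch scores to patch-level FC values
#'
#' The elementwise sigmoid of the raw linear patch scores: a monotone,
#' order-preserving map into (0, 1) so that color semantics match the
#' slide-level FC scale.
#'
#' @param patch_scores Numeric vector of raw patch scores.
#' @return Numeric vector in (0, 1).
#' @export
patch_fc_values <- function(patch_scores) {
  if (anyNA(patch_scores) || any(!is.finite(patch_scores))) {
    abort("`patch_scores` must be finite")
  }
  plogis(patch_scores)
}

#' Render a slide heatmap of patch-level FC values
#'
#' Kept cells are colored by linear interpolation between red (FC 0, loss)
#' and blue (FC 1, intact); omitted cells (background or blood) get a fixed
#' purple. Optionally writes a PNG with `cell_px` pixels per grid cell.
#'
#' @param grid Patch grid tibble (columns `row`, `col`, `status`), e.g.
#'   from [filter_patches()].
#' @param patch_fc FC values in \[0, 1\] for the kept cells, aligned with
#'   the kept rows of `grid` in order.
#' @param path Optional PNG output path.
#' @param cell_px Pixel block side per grid cell in the PNG.
#' @return A tibble of class `fc_heatmap`: one row per grid cell with
#'   `row`, `col`, `status`, `fc` (`NA` for omitted cells) and 8-bit `r`,
#'   `g`, `b` colors.
#' @export
render_heatmap <- function(grid, patch_fc, path = NULL, cell_px = 8L) {
  kept <- grid$status == "kept"
  if (sum(kept) != length(patch_fc)) {
    abort(sprintf("%d kept cells but %d FC values", sum(kept), length(patch_fc)))
  }
  if (length(patch_fc) && (any(patch_fc < 0) || any(patch_fc > 1))) {
    abort("`patch_fc` must lie in [0, 1]")
  }
  cells <- tibble::tibble(row = grid$row, col = grid$col, status = grid$status,
                          fc = NA_real_)
  cells$fc[kept] <- patch_fc
  cols <- matrix(rep(HEAT_PURPLE, each = nrow(cells)), ncol = 3)
  if (any(kept)) {
    t <- cells$fc[kept]
    for (ch in 1:3) {
      cols[kept, ch] <- (1 - t) * HEAT_RED[ch] + t * HEAT_BLUE[ch]
    }
  }
  cells$r <- cols[, 1]; cells$g <- cols[, 2]; cells$b <- cols[, 3]
  out <- structure(cells, class = c("fc_heatmap", class(cells)))
  if (!is.null(path)) {
    nr <- max(cells$row) + 1L; nc <- max(cells$col) + 1L
    img <- array(1, dim = c(nr, nc, 3))
    for (i in seq_len(nrow(cells))) {
      img[cells$row[i] + 1L, cells$col[i] + 1L, ] <- cols[i, ] / 255
    }
    big <- array(0, dim = c(nr * cell_px, nc * cell_px, 3))
    for (ch in 1:3) {
      big[, , ch] <- kronecker(img[, , ch], matrix(1, cell_px, cell_px))
    }
    png::writePNG(big, target = path)
  }
  out
}

#' @exportS3Method ggplot2::autoplot
autoplot.fc_heatmap <- function(object, ...) {
  object$hex <- grDevices::rgb(object$r, object$g, object$b, maxColorValue = 255)
  ggplot2::ggplot(object, ggplot2::aes(x = .data$col, y = -.data$row,
                                       fill = .data$hex)) +
    ggplot2::geom_tile() +
    ggplot2::scale_fill_identity() +
    ggplot2::coord_equal() +
    ggplot2::labs(x = NULL, y = NULL,
                  title = "Patch-level FC (red = loss, blue = intact, purple = omitted)") +
    ggplot2::theme_void()
}

#' Most extreme representative patches with their locations
#'
#' The `min(k, P)` highest- and `min(k, P)` lowest-scoring patches (the two
#' lists may overlap when P < 2k), each sorted by extremity with ties
#' broken toward the lower patch index.
#'
#' @param patch_scores Numeric vector of raw patch scores (length P >= 1).
#' @param coords Coordinate tibble aligned with `patch_scores` (columns
#'   `row`, `col`, `x0`, `y0`).
#' @param k Patches per side (default 100).
#' @return Tibble with `side` (`"high"`/`"low"`), `rank` (1 = most
#'   extreme), `patch_id`, coordinates and `score`.
#' @export
representative_patches <- function(patch_scores, coords, k = 100L) {
  P <- length(patch_scores)
  if (P < 1L) abort("`patch_scores` must be non-empty")
  if (nrow(coords) != P) abort("`coords` must align with `patch_scores`")
  kk <- min(k, P)
  ord_hi <- order(-patch_scores, seq_len(P))[seq_len(kk)]
  ord_lo <- order(patch_scores, seq_len(P))[seq_len(kk)]
  mk <- function(idx, side) {
    tibble::tibble(side = side, rank = seq_along(idx), patch_id = idx,
                   row = coords$row[idx], col = coords$col[idx],
                   x0 = coords$x0[idx], y0 = coords$y0[idx],
                   score = patch_scores[idx])
  }
  dplyr::bind_rows(mk(ord_hi, "high"), mk(ord_lo, "low"))
}
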