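BRICK_RGB <- list(
  red = c(200, 30, 30) / 255,
  blue = c(30, 60, 200) / 255,
  yellow = c(230, 200, 30) / 255,
  green = c(40, 160, 60) / 255,
  orange = c(235, 130, 25) / 255,
  white = c(245, 245, 245) / 255
)
SCENE_GRAY <- 140 / 255
BRICK_DIMS_CM <- list(small = c(0.8, 1.6), large = c(1.6, 2.4))

# Map world cm to scene pixel indices (row = y, col = x; row 1 is the
# table edge nearest the participant).
scene_dims <- function(layout) {
  c(h = ceiling(layout$image_size[2] * layout$pixel_scale /
                  layout$scene_pixel_scale),
    w = ceiling(layout$image_size[1] * layout$pixel_scale /
                  layout$scene_pixel_scale))
}

#' Render a synthetic table scene
#'
#' Draws saturated colored rectangles (bricks) on a uniform gray table and
#' returns an RGB array. Used by [generate_scene_pair()]; exported for
#' building activation-map fixtures.
#'
#' @param bricks A data frame with columns `x`, `y` (brick centers, cm),
#'   `size` (`"small"`/`"large"`) and `color` (one of red, blue, yellow,
#'   green, orange, white), plus optionally `w_cm`,
#'   `h_cm` to override the per-size footprint.
#' @param layout A [workspace_layout()].
#' @return An RGB array `[height, width, 3]` with values in \[0, 1\].
#' @export
render_scene <- function(bricks, layout = workspace_layout()) {
  dims <- scene_dims(layout)
  img <- array(SCENE_GRAY, dim = c(dims[["h"]], dims[["w"]], 3))
  if (is.null(bricks) || nrow(bricks) == 0L) return(img)
  occupied <- matrix(FALSE, dims[["h"]], dims[["w"]])
  warned <- FALSE
  sc <- layout$scene_pixel_scale
  for (i in seq_len(nrow(bricks))) {
    wh <- if (!is.null(bricks$w_cm)) {
      c(bricks$w_cm[i], bricks$h_cm[i])
    } else {
      BRICK_DIMS_CM[[bricks$size[i]]]
    }
    cols <- round((bricks$x[i] + c(-1, 1) * wh[1] / 2) / sc)
    rows <- round((bricks$y[i] + c(-1, 1) * wh[2] / 2) / sc)
    cols <- pmin(pmax(cols, 1L), dims[["w"]])
    rows <- pmin(pmax(rows, 1L), dims[["h"]])
    rr <- rows[1]:rows[2]; cc <- cols[1]:cols[2]
    if (!warned && any(occupied[rr, cc])) {
      warning("overlapping bricks in scene", call. = FALSE)
      warned <- TRUE
    }
    occupied[rr, cc] <- TRUE
    rgb <- BRICK_RGB[[bricks$color[i]]]
    for (ch in 1:3) img[rr, cc, ch] <- rgb[ch]
  }
  img
}

#' Generate a start/end scene-image pair
#'
#' Produces the pair of RGB images that bracket a trial: the start image
#' shows all bricks in place on the picking pad; the end image lacks the
#' picked bricks there and shows them at their deposit locations on the
#' placing pad. Bricks that were not acted on (`static`) appear
#' identically in both images and therefore cancel in the difference-image
#' analysis.
#'
#' @param layout A [workspace_layout()].
#' @param placed_positions Data frame (`x`, `y`, `size`, `color`) of
#'   deposited bricks on the placing pad.
#' @param picked_positions Data frame of the same bricks at their original
#'   positions on the picking pad.
#' @param seed Integer seed (controls the random in-plane orientation of
#'   each brick footprint); the output is bit-identical for equal inputs
#'   and seed.
#' @param static Optional data frame of bricks present in both images.
#'
#' @return A list with RGB arrays `start` and `end`.
#' @export
generate_scene_pair <- function(layout = workspace_layout(),
                                placed_positions = NULL,
                                picked_positions = NULL,
                                seed = 1L, static = NULL) {
  pp <- function(df, pad) {
    if (is.null(df) || nrow(df) == 0L) return(invisible(NULL))
    if (!all(rect_contains(pad, df$x, df$y))) {
      stop("brick positions must lie on their pad", call. = FALSE)
    }
  }
  pp(picked_positions, layout$picking_pad)
  pp(placed_positions, layout$placing_pad)

  old <- if (exists(".Random.seed", envir = globalenv())) {
    get(".Random.seed", envir = globalenv())
  } else NULL
  on.exit({
    if (!is.null(old)) assign(".Random.seed", old, envir = globalenv())
  }, add = TRUE)
  set.seed(seed)

  orient <- function(df) {
    if (is.null(df) || nrow(df) == 0L) return(df)
    dims <- t(vapply(df$size, function(s) BRICK_DIMS_CM[[s]], numeric(2)))
    flip <- stats::runif(nrow(df)) < 0.5
    df$w_cm <- ifelse(flip, dims[, 2], dims[, 1])
    df$h_cm <- ifelse(flip, dims[, 1], dims[, 2])
    df
  }
  static <- orient(static)
  picked <- orient(picked_positions)
  placed <- orient(placed_positions)

  start_img <- render_scene(dplyr::bind_rows(static, picked), layout)
  end_img <- render_scene(dplyr::bind_rows(static, placed), layout)
  list(start = start_img, end = end_img)
}

#' Write a scene image to PNG
#'
#' @param img RGB array as returned by [render_scene()].
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_scene_png <- function(img, path) {
  png::writePNG(img, path)
  invisible(path)
}

#' Read a scene image from PNG
#'
#' @param path PNG file path.
#' @return RGB array `[height, width, 3]` in \[0, 1\].
#' @export
read_scene_png <- function(path) {
  img <- png::readPNG(path)
  if (length(dim(img)) == 2L) img <- array(rep(img, 3), c(dim(img), 3))
  img[, , 1:3, drop = FALSE] |> array(dim = c(dim(img)[1:2], 3))
}
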