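#' Binarize a scene image by saturation and value
#'
#' Converts an RGB image to HSV and keeps only pixels that are both
#' saturated and bright (S and V above their thresholds on the 0-255
#' scale): colored bricks survive, the gray table and mild lighting
#' artifacts are removed. Surviving pixels are set to 255, the rest to 0.
#'
#' @param img RGB array `[height, width, 3]` with values in \[0, 1\].
#' @param s_threshold,v_threshold Thresholds on the 0-255 HSV scale
#'   (default 50).
#' @return Numeric matrix of 0/255 values.
#' @export
binarize_scene <- function(img, s_threshold = 50, v_threshold = 50) {
  if (length(dim(img)) != 3L || dim(img)[3] < 3L) {
    stop("expected an RGB array [h, w, 3]", call. = FALSE)
  }
  d <- dim(img)
  rgb <- rbind(as.vector(img[, , 1]), as.vector(img[, , 2]),
               as.vector(img[, , 3]))
  hsv <- grDevices::rgb2hsv(rgb, maxColorValue = 1)
  keep <- hsv[2, ] > s_threshold / 255 & hsv[3, ] > v_threshold / 255
  matrix(ifelse(keep, 255, 0), d[1], d[2])
}

gaussian_blur <- function(mat, radius = 5) {
  EBImage::gblur(mat, sigma = radius, boundary = "replicate")
}

# cm rectangle -> scene pixel row/col ranges
crop_indices <- function(rect, layout) {
  sc <- layout$scene_pixel_scale
  dims <- scene_dims(layout)
  rows <- pmin(pmax(round(c(rect[["ymin"]], rect[["ymax"]]) / sc), 1L),
               dims[["h"]])
  cols <- pmin(pmax(round(c(rect[["xmin"]], rect[["xmax"]]) / sc), 1L),
               dims[["w"]])
  list(rows = rows[1]:rows[2], cols = cols[1]:cols[2])
}

#' Difference-image activation map of a pad
#'
#' Quantifies where objects appeared or disappeared between the start and
#' end images of a trial over one pad. Both images are cropped to the pad,
#' binarized by saturation/value ([binarize_scene()]) and Gaussian-blurred
#' (radius 5 px); the blurred images are subtracted (absolute difference),
#' normalized to 0-255 by the image maximum, blurred again, floored
#' (values below 150 set to zero, removing lighting artifacts and objects
#' that only shifted slightly), blurred a final time and rescaled to a
#' 0-100% activation scale.
#'
#' @param start_img,end_img RGB arrays of the same size, values in
#'   \[0, 1\].
#' @param area `"picking"` or `"placing"` (selects the crop rectangle).
#' @param layout A [workspace_layout()].
#' @param blur_radius Gaussian blur radius in px (default 5; the radius is
#'   used as the Gaussian sigma).
#' @param floor_value Threshold on the 0-255 scale below which differences
#'   are zeroed (default 150).
#' @param s_threshold,v_threshold Passed to [binarize_scene()].
#' @return An object of class `activation_map`: list with `area`,
#'   `values` (matrix on the 0-100 scale), `quadrant_means`
#'   ([quadrant_means()]) and `crop_rect` (pad rectangle, cm).
#' @export
activation_map <- function(start_img, end_img,
                           area = c("picking", "placing"),
                           layout = workspace_layout(),
                           blur_radius = 5, floor_value = 150,
                           s_threshold = 50, v_threshold = 50) {
  area <- match.arg(area)
  if (!identical(dim(start_img), dim(end_img))) {
    stop("start and end images must have identical size", call. = FALSE)
  }
  pad <- if (area == "picking") layout$picking_pad else layout$placing_pad
  ci <- crop_indices(pad, layout)
  crop <- function(img) img[ci$rows, ci$cols, , drop = FALSE]
  b1 <- gaussian_blur(binarize_scene(crop(start_img), s_threshold,
                                     v_threshold), blur_radius)
  b2 <- gaussian_blur(binarize_scene(crop(end_img), s_threshold,
                                     v_threshold), blur_radius)
  d <- abs(b1 - b2)
  mx <- max(d)
  if (mx > 0) d <- d / mx * 255
  d <- gaussian_blur(d, blur_radius)
  d[d < floor_value] <- 0
  d <- gaussian_blur(d, blur_radius)
  vals <- pmin(pmax(d / 255 * 100, 0), 100)
  out <- structure(
    list(area = area, values = vals, quadrant_means = NULL,
         crop_rect = pad),
    class = "activation_map"
  )
  out$quadrant_means <- quadrant_means(out)
  out
}

#' Mean activation per pad quadrant
#'
#' Splits the activation map into four equally sized quadrants (1 =
#' far-left, 2 = far-right, 3 = near-left, 4 = near-right; with odd
#' dimensions the spare row/column is assigned to the near/right
#' quadrants) and returns the mean activation of each.
#'
#' @param map An [activation_map()], or a plain matrix whose first row
#'   corresponds to the near (participant) side and first column to the
#'   left side.
#' @return Named numeric vector `q1`..`q4` on the map's 0-100 scale.
#' @export
quadrant_means <- function(map) {
  vals <- if (inherits(map, "activation_map")) map$values else map
  h <- nrow(vals); w <- ncol(vals)
  near <- seq_len(ceiling(h / 2)) # row 1 = near side
  far <- setdiff(seq_len(h), near)
  left <- seq_len(floor(w / 2))
  right <- setdiff(seq_len(w), left)
  c(q1 = mean(vals[far, left]), q2 = mean(vals[far, right]),
    q3 = mean(vals[near, left]), q4 = mean(vals[near, right]))
}

#' Quadrant activations across a cohort
#'
#' Renders each trial's scene pair, computes the picking- (or placing-)
#' pad activation map and returns the quadrant means per trial, ready for
#' aggregation and spatial-preference statistics.
#'
#' @param cohort A [generate_cohort()] result with tracks.
#' @param area `"picking"` or `"placing"`.
#' @param trial_ids Subset of trials (default: all).
#' @return Tibble with `participant_id`, `trial_id`, `instruction`,
#'   `search_size`, `q1`..`q4`.
#' @export
activation_cohort <- function(cohort, area = c("picking", "placing"),
                              trial_ids = NULL) {
  area <- match.arg(area)
  if (is.null(trial_ids)) trial_ids <- names(cohort$ground_truth)
  meta <- cohort$trials[match(trial_ids, cohort$trials$trial_id), ]
  rows <- lapply(seq_along(trial_ids), function(i) {
    pair <- cohort_scene_pair(cohort, trial_ids[i])
    qm <- activation_map(pair$start, pair$end, area,
                         cohort$layout)$quadrant_means
    tibble::tibble(
      participant_id = meta$participant_id[i], trial_id = trial_ids[i],
      instruction = meta$instruction[i], search_size = meta$search_size[i],
      q1 = qm[["q1"]], q2 = qm[["q2"]], q3 = qm[["q3"]], q4 = qm[["q4"]]
    )
  })
  dplyr::bind_rows(rows)
}
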