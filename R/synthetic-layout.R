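#' Rectangular regions
#'
#' Regions on the table are axis-aligned rectangles in table coordinates
#' (cm), encoded as named numeric vectors `c(xmin, xmax, ymin, ymax)`.
#' x runs from the participant's left to right, y from the table edge in
#' front of the participant (y = 0) away from them.
#'
#' @param xmin,xmax,ymin,ymax Rectangle bounds in cm.
#' @return A named numeric vector of class `region_rect`.
#' @export
region_rect <- function(xmin, xmax, ymin, ymax) {
  if (!(xmax > xmin && ymax > ymin)) {
    stop("degenerate region: need xmax > xmin and ymax > ymin", call. = FALSE)
  }
  structure(c(xmin = xmin, xmax = xmax, ymin = ymin, ymax = ymax),
            class = "region_rect")
}

rect_center <- function(r) c((r[["xmin"]] + r[["xmax"]]) / 2,
                             (r[["ymin"]] + r[["ymax"]]) / 2)

rect_contains <- function(r, x, y) {
  x >= r[["xmin"]] & x <= r[["xmax"]] & y >= r[["ymin"]] & y <= r[["ymax"]]
}

#' Euclidean distance from points to a rectangle
#'
#' Zero for points inside the rectangle.
#'
#' @param r A [region_rect()].
#' @param x,y Point coordinates (cm), vectorised.
#' @return Numeric vector of distances (cm).
#' @export
rect_distance <- function(r, x, y) {
  dx <- pmax(r[["xmin"]] - x, 0, x - r[["xmax"]])
  dy <- pmax(r[["ymin"]] - y, 0, y - r[["ymax"]])
  sqrt(dx^2 + dy^2)
}

#' Workspace layout of the foraging table
#'
#' Describes the geometry of the experimental workspace as seen by the
#' overhead camera: a picking pad (right) where bricks are presented, a
#' placing pad (left) where they are deposited, and a small start key on
#' the participant's midline between the pads. Defaults follow the
#' apparatus: 22 x 30 cm pads with the short side facing the participant,
#' a 16 cm gap between the pads, pads 5.5 cm from the table edge, the
#' 3 x 3 cm start key 3.5 cm from the edge, a 1440 x 1080 px camera at
#' 0.042 cm/px so the field of view spans the 60 cm pad arrangement.
#'
#' @param pad_width,pad_depth Pad extent in cm (x and y respectively).
#' @param pad_gap Gap between the two pads in cm.
#' @param pad_edge_offset Distance from table edge to the pads (cm).
#' @param key_size Side length of the square start key (cm).
#' @param key_edge_offset Distance from table edge to the key (cm).
#' @param pixel_scale Camera calibration, cm per pixel.
#' @param image_size Camera resolution `c(width, height)` in pixels.
#' @param scene_pixel_scale Rendering scale for synthetic scene images,
#'   cm per pixel. Coarser than the camera so that full-scene images stay
#'   small; all activation-map parameters are expressed in these pixels.
#'
#' @return A list of class `workspace_layout` with regions `picking_pad`,
#'   `placing_pad`, `start_key` (all [region_rect()]) and the calibration
#'   fields.
#' @examples
#' lay <- workspace_layout()
#' lay$picking_pad
#' @export
workspace_layout <- function(pad_width = 22, pad_depth = 30, pad_gap = 16,
                             pad_edge_offset = 5.5, key_size = 3,
                             key_edge_offset = 3.5,
                             pixel_scale = 0.042,
                             image_size = c(1440, 1080),
                             scene_pixel_scale = 0.1) {
  world_w <- image_size[1] * pixel_scale
  cx <- world_w / 2
  placing <- region_rect(cx - pad_gap / 2 - pad_width, cx - pad_gap / 2,
                         pad_edge_offset, pad_edge_offset + pad_depth)
  picking <- region_rect(cx + pad_gap / 2, cx + pad_gap / 2 + pad_width,
                         pad_edge_offset, pad_edge_offset + pad_depth)
  key <- region_rect(cx - key_size / 2, cx + key_size / 2,
                     key_edge_offset, key_edge_offset + key_size)
  if (placing[["xmax"]] > picking[["xmin"]]) {
    stop("invalid layout: pads overlap", call. = FALSE)
  }
  structure(
    list(picking_pad = picking, placing_pad = placing, start_key = key,
         pad_size = c(pad_width, pad_depth), pad_gap = pad_gap,
         pixel_scale = pixel_scale, image_size = image_size,
         scene_pixel_scale = scene_pixel_scale),
    class = "workspace_layout"
  )
}

#' Quadrants of a pad
#'
#' Splits a pad into four equally sized quadrants for spatial-preference
#' analysis, labelled 1 = far-left, 2 = far-right, 3 = near-left,
#' 4 = near-right ("near" meaning closer to the participant, i.e. smaller
#' y; "left" meaning smaller x).
#'
#' @param pad A [region_rect()].
#' @return A list of four [region_rect()]s named `q1`..`q4`.
#' @export
pad_quadrants <- function(pad) {
  mx <- (pad[["xmin"]] + pad[["xmax"]]) / 2
  my <- (pad[["ymin"]] + pad[["ymax"]]) / 2
  list(
    q1 = region_rect(pad[["xmin"]], mx, my, pad[["ymax"]]),
    q2 = region_rect(mx, pad[["xmax"]], my, pad[["ymax"]]),
    q3 = region_rect(pad[["xmin"]], mx, pad[["ymin"]], my),
    q4 = region_rect(mx, pad[["xmax"]], pad[["ymin"]], my)
  )
}

#' @keywords internal
which_quadrant <- function(pad, x, y) {
  mx <- (pad[["xmin"]] + pad[["xmax"]]) / 2
  my <- (pad[["ymin"]] + pad[["ymax"]]) / 2
  left <- x < mx
  near <- y < my
  ifelse(near, ifelse(left, 3L, 4L), ifelse(left, 1L, 2L))
}
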