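#' Keypoint tracks
#'
#' A `keypoint_track` holds the per-frame output of a markerless pose
#' estimator for a single joint: pixel coordinates `x`, `y` and the
#' estimator's confidence (`likelihood`, in \[0, 1\]) for every video frame,
#' together with the acquisition frame rate and the spatial calibration of
#' the camera.
#'
#' @param x,y Numeric vectors of pixel coordinates, one value per frame.
#' @param likelihood Numeric vector of per-frame confidence scores in
#'   \[0, 1\]. Defaults to 1 for every frame.
#' @param fps Frame rate in frames per second (default 200).
#' @param pixel_scale Spatial calibration in cm per pixel (default 0.042).
#' @param joint Name of the tracked joint. The conventional choice for this
#'   pipeline is the metacarpophalangeal joint of the right index finger,
#'   abbreviated `"index_mcp"`.
#'
#' @return An object of class `keypoint_track`: a list with elements `x`,
#'   `y`, `likelihood`, `fps`, `pixel_scale` and `joint`.
#' @examples
#' trk <- keypoint_track(x = c(0, 3, 6), y = c(0, 4, 8))
#' n_frames(trk)
#' @export
keypoint_track <- function(x, y, likelihood = rep(1, length(x)),
                           fps = 200, pixel_scale = 0.042,
                           joint = "index_mcp") {
  x <- as.numeric(x)
  y <- as.numeric(y)
  likelihood <- as.numeric(likelihood)
  if (length(x) != length(y) || length(x) != length(likelihood)) {
    stop("`x`, `y` and `likelihood` must have equal length", call. = FALSE)
  }
  if (!is.numeric(fps) || length(fps) != 1L || fps <= 0) {
    stop("`fps` must be a single positive number", call. = FALSE)
  }
  if (!is.numeric(pixel_scale) || length(pixel_scale) != 1L || pixel_scale <= 0) {
    stop("`pixel_scale` must be a single positive number", call. = FALSE)
  }
  ok <- is.na(likelihood) | (likelihood >= 0 & likelihood <= 1)
  if (!all(ok)) stop("`likelihood` values must lie in [0, 1]", call. = FALSE)
  structure(
    list(x = x, y = y, likelihood = likelihood,
         fps = fps, pixel_scale = pixel_scale, joint = as.character(joint)),
    class = "keypoint_track"
  )
}

#' @rdname keypoint_track
#' @param track A `keypoint_track`.
#' @export
n_frames <- function(track) {
  stopifnot(inherits(track, "keypoint_track"))
  length(track$x)
}

#' @export
print.keypoint_track <- function(x, ...) {
  cat(sprintf(
    "<keypoint_track> joint '%s': %d frames @ %g fps, %g cm/px\n",
    x$joint, length(x$x), x$fps, x$pixel_scale
  ))
  invisible(x)
}

#' Read and write keypoint tracks
#'
#' Keypoint tracks are stored as plain CSV in long ("tidy") form with one
#' row per frame and joint and columns `frame`, `joint`, `x`, `y`,
#' `likelihood`. `frame` is 1-based. This is the on-disk format written by
#' [write_keypoint_track()] and by the synthetic-data generator, and is a
#' direct reshaping of the per-joint x/y/likelihood tables produced by
#' common markerless pose estimators.
#'
#' @param path Path to a keypoint CSV file.
#' @param joint Joint name to extract (default `"index_mcp"`).
#' @param fps,pixel_scale Calibration to attach to the returned track.
#'
#' @return [load_keypoint_track()] returns a [keypoint_track()];
#'   [write_keypoint_track()] returns `path` invisibly.
#' @export
load_keypoint_track <- function(path, joint = "index_mcp",
                                fps = 200, pixel_scale = 0.042) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("frame", "joint", "x", "y", "likelihood")
  if (!all(need %in% names(df))) {
    stop("malformed keypoint file: expected columns ",
         paste(need, collapse = ", "), call. = FALSE)
  }
  df <- df[df$joint == joint, , drop = FALSE]
  if (nrow(df) == 0L) {
    stop("joint not found in file: '", joint, "'", call. = FALSE)
  }
  df <- df[order(df$frame), , drop = FALSE]
  keypoint_track(df$x, df$y, df$likelihood,
                 fps = fps, pixel_scale = pixel_scale, joint = joint)
}

#' @rdname load_keypoint_track
#' @param track A [keypoint_track()] to write.
#' @export
write_keypoint_track <- function(track, path) {
  stopifnot(inherits(track, "keypoint_track"))
  df <- data.frame(
    frame = seq_along(track$x), joint = track$joint,
    x = track$x, y = track$y, likelihood = track$likelihood
  )
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' Repair low-confidence samples by linear interpolation
#'
#' Frames whose likelihood score falls below `threshold` are treated as
#' tracking dropouts: their x and y coordinates are replaced by linear
#' interpolation between the nearest flanking confident frames. Confident
#' frames are never altered. Dropout runs at the very start or end of the
#' track, where there is no flanking frame on one side, are filled with the
#' nearest confident value (no extrapolation).
#'
#' @param track A [keypoint_track()].
#' @param threshold Likelihood below which a frame is repaired (default 0.7).
#'
#' @return A [keypoint_track()] with repaired coordinates; the likelihood
#'   series is kept unchanged so that downstream stages can still see which
#'   frames were estimated.
#' @examples
#' trk <- keypoint_track(x = c(0, 99, 10), y = c(0, 99, 0),
#'                       likelihood = c(0.99, 0.2, 0.99))
#' interpolate_low_confidence(trk)$x  # middle sample becomes 5
#' @export
interpolate_low_confidence <- function(track, threshold = 0.7) {
  stopifnot(inherits(track, "keypoint_track"))
  good <- which(track$likelihood >= threshold)
  if (length(good) == 0L) {
    stop("unrecoverable track: no frame at or above the likelihood threshold",
         call. = FALSE)
  }
  n <- length(track$x)
  if (length(good) == n) return(track)
  idx <- seq_len(n)
  # rule = 2: nearest-value extension for leading/trailing dropout runs
  track$x <- stats::approx(good, track$x[good], xout = idx, rule = 2)$y
  track$y <- stats::approx(good, track$y[good], xout = idx, rule = 2)$y
  track
}

#' Convert a track to physical units
#'
#' Maps pixels to centimetres via the track's `pixel_scale` and frame
#' indices to milliseconds via its frame rate: frame *i* (1-based) occurs at
#' `(i - 1) * 1000 / fps` ms, so frame 1 is time 0.
#'
#' @param track A [keypoint_track()].
#' @return A [tibble::tibble] with columns `frame`, `time_ms`, `x_cm`,
#'   `y_cm`, `likelihood`.
#' @examples
#' trk <- keypoint_track(x = rep(0, 50), y = rep(0, 50))
#' range(to_physical(trk)$time_ms)  # 50 frames at 200 fps span 0..245 ms
#' @export
to_physical <- function(track) {
  stopifnot(inherits(track, "keypoint_track"))
  if (is.null(track$pixel_scale) || is.null(track$fps)) {
    stop("track is missing calibration (`pixel_scale`/`fps`)", call. = FALSE)
  }
  n <- length(track$x)
  tibble::tibble(
    frame = seq_len(n),
    time_ms = (seq_len(n) - 1) * 1000 / track$fps,
    x_cm = track$x * track$pixel_scale,
    y_cm = track$y * track$pixel_scale,
    likelihood = track$likelihood
  )
}

#' Frame/time conversion helpers
#'
#' @param frames Number of frames (a duration, not an index).
#' @param fps Frame rate in frames per second.
#' @return Duration in milliseconds.
#' @examples
#' frames_to_ms(50, 200)  # 250 ms
#' @export
frames_to_ms <- function(frames, fps = 200) frames * 1000 / fps
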