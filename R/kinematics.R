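#' Per-frame movement speed
#'
#' Speed is the pixelwise Euclidean distance between the hand position in
#' consecutive frames, `sqrt((x[i+1]-x[i])^2 + (y[i+1]-y[i])^2)`, in native
#' units of px/frame. The difference is attributed to the later frame and
#' the first element is duplicated so that the speed series has the same
#' length as the track, which keeps elementwise products with per-frame
#' probability signals aligned during segmentation.
#'
#' @param track A [keypoint_track()] with at least 2 frames.
#' @return Numeric vector of speeds (px/frame), same length as the track.
#' @examples
#' trk <- keypoint_track(x = c(0, 3), y = c(0, 4))
#' compute_speed(trk)  # 5 px/frame (3-4-5 triangle)
#' @export
compute_speed <- function(track) {
  stopifnot(inherits(track, "keypoint_track"))
  if (length(track$x) < 2L) {
    stop("track must have at least 2 frames", call. = FALSE)
  }
  s <- sqrt(diff(track$x)^2 + diff(track$y)^2)
  c(s[1], s)
}

#' Convert speeds between native and physical units
#'
#' @param speed Speed in px/frame.
#' @param pixel_scale cm per pixel.
#' @param fps Frames per second.
#' @return Speed in cm/s.
#' @examples
#' speed_to_cm_s(5, 0.042, 200)  # 42 cm/s
#' @export
speed_to_cm_s <- function(speed, pixel_scale = 0.042, fps = 200) {
  speed * pixel_scale * fps
}

#' Savitzky-Golay smoothing
#'
#' Polynomial least-squares smoothing of a series, preserving its length.
#' The default third-order filter with a 59-frame window (295 ms at 200
#' fps) removes frame-to-frame tracking jitter while reproducing cubic
#' trends exactly. Edges are handled by the filter's built-in polynomial
#' fit over the first and last window rather than by wrap-around, so
#' movement onsets near the track boundaries are not contaminated.
#'
#' @param series Numeric vector, at least `window` long.
#' @param order Polynomial order (default 3).
#' @param window Odd window length in frames (default 59); must exceed
#'   `order`.
#' @return Smoothed numeric vector, same length as the input.
#' @export
smooth_series <- function(series, order = 3, window = 59) {
  if (window %% 2 == 0) stop("`window` must be odd", call. = FALSE)
  if (window <= order) stop("`window` must exceed `order`", call. = FALSE)
  if (length(series) < window) {
    stop("series shorter than the smoothing window (", length(series),
         " < ", window, ")", call. = FALSE)
  }
  as.numeric(signal::sgolayfilt(series, p = order, n = window))
}

#' Per-frame acceleration of the smoothed speed
#'
#' Computed as the central-difference gradient of the smoothed speed
#' (one-sided differences at the two ends), then smoothed again with the
#' same Savitzky-Golay filter. Native units are px/frame^2.
#'
#' @param smoothed_speed Numeric vector of smoothed speeds.
#' @inheritParams smooth_series
#' @return Numeric vector of accelerations, same length as the input.
#' @export
compute_acceleration <- function(smoothed_speed, order = 3, window = 59) {
  n <- length(smoothed_speed)
  if (n < 3L) stop("need at least 3 samples", call. = FALSE)
  g <- numeric(n)
  g[1] <- smoothed_speed[2] - smoothed_speed[1]
  g[n] <- smoothed_speed[n] - smoothed_speed[n - 1]
  g[2:(n - 1)] <- (smoothed_speed[3:n] - smoothed_speed[1:(n - 2)]) / 2
  smooth_series(g, order = order, window = window)
}

#' Full kinematic series for a track
#'
#' Convenience wrapper computing raw speed, smoothed speed and smoothed
#' acceleration in one call.
#'
#' @param track A [keypoint_track()].
#' @inheritParams smooth_series
#' @return A list of class `kinematic_series` with elements `speed`,
#'   `smoothed_speed`, `acceleration` (all px/frame or px/frame^2, same
#'   length as the track), plus the smoothing settings.
#' @export
kinematic_series <- function(track, order = 3, window = 59) {
  speed <- compute_speed(track)
  sm <- smooth_series(speed, order = order, window = window)
  acc <- compute_acceleration(sm, order = order, window = window)
  structure(
    list(speed = speed, smoothed_speed = sm, acceleration = acc,
         smoothing_order = order, smoothing_window = window),
    class = "kinematic_series"
  )
}
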