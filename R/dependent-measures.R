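#' Deceleration time of a movement
#'
#' Percentage of a movement's duration spent after its peak speed,
#' `100 * (n_end - n_peak) / (n_end - n_start)`, where the peak is the
#' *first* frame attaining the maximum (deterministic under ties). Longer
#' deceleration times indicate a more careful approach.
#'
#' @param speed Numeric vector of (smoothed) speeds over the movement,
#'   one value per frame.
#' @return Deceleration time in percent, in \[0, 100\].
#' @examples
#' deceleration_time(c(0, 1, 2, 3, 2, 1, 0))  # symmetric peak: 50
#' deceleration_time(1:5)                      # peak at the end: 0
#' @export
deceleration_time <- function(speed) {
  n <- length(speed)
  if (n < 2L) stop("segment must span at least 2 frames", call. = FALSE)
  100 * (n - which.max(speed)) / (n - 1)
}

#' Path ratio of a movement
#'
#' Traveled path length divided by the straight-line distance between the
#' movement's endpoints; 1 for a perfectly straight reach.
#'
#' @param x,y Position coordinates over the movement (any consistent
#'   unit).
#' @return Dimensionless ratio `>= 1` up to measurement noise.
#' @examples
#' th <- seq(0, pi, length.out = 200)
#' path_ratio(cos(th), sin(th))  # semicircle: pi/2
#' @export
path_ratio <- function(x, y) {
  n <- length(x)
  stopifnot(length(y) == n, n >= 2L)
  direct <- sqrt((x[n] - x[1])^2 + (y[n] - y[1])^2)
  if (direct < sqrt(.Machine$double.eps)) {
    stop("path ratio undefined: coincident endpoints", call. = FALSE)
  }
  sum(sqrt(diff(x)^2 + diff(y)^2)) / direct
}

#' Movement onset relative to the audio instruction
#'
#' Time between the end of the audio instruction and the detected start
#' of the first reach movement. Negative onsets (the hand moved before
#' the instruction finished) are retained and flagged via the
#' `"early_start"` attribute rather than clamped.
#'
#' @param first_reach_start_frame 1-based frame of the first reach start.
#' @param audio_end_time_ms End of the audio instruction in ms from
#'   recording onset.
#' @param fps Frame rate.
#' @return Onset in ms (possibly negative), with attribute
#'   `early_start`.
#' @examples
#' movement_onset(113, 0)  # frame 113 at 200 fps: 560 ms
#' @export
movement_onset <- function(first_reach_start_frame, audio_end_time_ms,
                           fps = 200) {
  if (is.na(audio_end_time_ms)) {
    stop("missing audio end time in trial metadata", call. = FALSE)
  }
  onset <- (first_reach_start_frame - 1) * 1000 / fps - audio_end_time_ms
  structure(onset, early_start = onset < 0)
}

#' Kinematic summary of one movement segment
#'
#' Computes the per-movement dependent variables: duration (frames
#' converted to ms), average and peak of the smoothed speed (converted to
#' cm/s), deceleration time (percent of duration after peak smoothed
#' speed), traveled distance (summed per-frame Euclidean steps converted
#' to cm) and path ratio.
#'
#' @param track The trial's [keypoint_track()] (interpolated).
#' @param segment One row of a segmentation result (fields `start_frame`,
#'   `end_frame`, and optionally `phase`, `index`).
#' @param kin A [kinematic_series()] for the track (recomputed if
#'   omitted).
#' @param raw_peak Use the raw rather than smoothed speed for the peak.
#' @return A one-row [tibble::tibble] with `phase`, `index`,
#'   `duration_ms`, `avg_speed_cm_s`, `peak_speed_cm_s`,
#'   `deceleration_pct`, `distance_cm`, `path_ratio`.
#' @export
summarize_segment <- function(track, segment, kin = NULL,
                              raw_peak = FALSE) {
  stopifnot(inherits(track, "keypoint_track"))
  s <- as.integer(segment$start_frame)
  e <- as.integer(segment$end_frame)
  n <- length(track$x)
  if (is.na(s) || is.na(e) || s < 1L || e > n || e - s < 1L) {
    stop("invalid segment bounds [", s, ", ", e, "]", call. = FALSE)
  }
  if (is.null(kin)) kin <- kinematic_series(track)
  idx <- s:e
  sm <- kin$smoothed_speed[idx]
  sp <- if (raw_peak) kin$speed[idx] else sm
  steps <- sqrt(diff(track$x[idx])^2 + diff(track$y[idx])^2)
  pr <- tryCatch(path_ratio(track$x[idx], track$y[idx]),
                 error = function(err) NA_real_)
  tibble::tibble(
    phase = if (!is.null(segment$phase)) as.character(segment$phase) else NA_character_,
    index = if (!is.null(segment$index)) as.integer(segment$index) else NA_integer_,
    duration_ms = (e - s) * 1000 / track$fps,
    avg_speed_cm_s = speed_to_cm_s(mean(sm), track$pixel_scale, track$fps),
    peak_speed_cm_s = speed_to_cm_s(max(sp), track$pixel_scale, track$fps),
    deceleration_pct = deceleration_time(sm),
    distance_cm = sum(steps) * track$pixel_scale,
    path_ratio = pr
  )
}

#' Dependent variables for all segments of a trial
#'
#' Applies [summarize_segment()] to every segment of a
#' [segment_trial()] result and attaches the trial-level movement onset
#' (first reach only).
#'
#' @param track The trial's [keypoint_track()].
#' @param segmentation A `trial_segmentation` from [segment_trial()].
#' @param audio_end_time_ms Audio-instruction end for the onset measure
#'   (NA to skip).
#' @return A tibble with one row per segment plus an `onset_ms` column
#'   (non-NA only on the first reach row).
#' @export
measure_trial <- function(track, segmentation, audio_end_time_ms = NA) {
  segs <- segmentation$segments
  if (nrow(segs) == 0L) {
    return(tibble::tibble())
  }
  kin <- kinematic_series(track)
  rows <- lapply(seq_len(nrow(segs)), function(i) {
    out <- summarize_segment(track, segs[i, ], kin)
    out$trial_id <- segs$trial_id[i]
    out$start_frame <- segs$start_frame[i]
    out$end_frame <- segs$end_frame[i]
    out
  })
  out <- dplyr::bind_rows(rows)
  out$onset_ms <- NA_real_
  first_reach <- which(out$phase == "reach" & out$index == 1L)
  if (length(first_reach) && !is.na(audio_end_time_ms)) {
    out$onset_ms[first_reach[1]] <- as.numeric(
      movement_onset(out$start_frame[first_reach[1]], audio_end_time_ms,
                     fps = track$fps)
    )
  }
  out
}
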