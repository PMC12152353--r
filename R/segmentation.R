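#' Segmentation configuration
#'
#' All tunables of the objective-function movement segmentation. The
#' printed thresholds of the original procedure are kept: a 30 speed
#' threshold, a 0.5 cm/frame^2 acceleration ceiling, a 0.9 likelihood
#' threshold, Gaussian event weights of SD 9 frames, mutual-suppression
#' windows offset by 100 frames, and a 50-frame minimum peak distance.
#'
#' The speed threshold is interpreted in cm/s by default
#' (`speed_threshold_unit = "cm_s"`): a literal 30 cm *per frame* at 200
#' fps would correspond to 6 m/s across a 30 cm pad and can never be
#' reached by a hand movement, so the per-second reading is the physically
#' meaningful one. Set `speed_threshold_unit = "cm_frame"` to apply the
#' threshold to cm/frame values instead.
#'
#' @param speed_threshold Speed a movement must exceed to count as started
#'   (default 30, see `speed_threshold_unit`).
#' @param speed_threshold_unit `"cm_s"` (default) or `"cm_frame"`.
#' @param accel_threshold Acceleration magnitude ceiling in cm/frame^2
#'   used to reject tracking artifacts (default 0.5; real reaches stay two
#'   orders of magnitude below it).
#' @param likelihood_threshold Minimum pose likelihood at an event frame
#'   (default 0.9).
#' @param position_sd Gaussian decay scale (cm) of the region-proximity
#'   signal outside its region (default 3).
#' @param shifted_gaussian_sd SD (frames) of the Gaussian event weights
#'   placed at speed-threshold crossings (default 9).
#' @param shifted_gaussian_shift Shift (frames) from a threshold crossing
#'   back (starts) or forward (ends) to the expected boundary (default 13).
#' @param suppression_offset Frames between a movement start and the
#'   window in which its end is expected, and vice versa (default 100).
#' @param suppression_sd SD (frames) of the mutual-suppression windows
#'   (default 9).
#' @param suppression_floor Baseline retained outside suppression windows
#'   (default 0.05), so suppression down-weights rather than erases.
#' @param peak_min_distance Minimum frames between detected events
#'   (default 50).
#' @param peak_min_height Minimum objective value of a detected event
#'   (default 0.1).
#' @param gate_slack Relative softness of the threshold gates: logistic
#'   slope scale as a fraction of the threshold (default 0.1). Ignored
#'   when `hard_gates = TRUE`.
#' @param hard_gates Use 0/1 indicator gates instead of soft logistic
#'   gates.
#' @param gate_window Frames ahead (starts) / behind (ends) over which the
#'   speed threshold must be exceeded (default 50).
#' @param refine_rel,refine_floor Boundary refinement: a detected event is
#'   snapped to the frame where lightly smoothed speed crosses
#'   `max(refine_rel * leg peak, refine_floor, refine_noise_mult * noise)`
#'   (relative fraction, absolute floor in cm/s).
#' @param refine_noise_mult Multiplier on the trial's stationary-speed
#'   level (10th percentile of lightly smoothed speed) entering the
#'   refinement threshold.
#' @param refine_window Frames around an event searched for its movement
#'   leg during refinement.
#' @param refine_smooth_window Window (frames) of the light smoothing used
#'   for refinement.
#' @param smoothing_order,smoothing_window Savitzky-Golay settings for the
#'   speed/acceleration series (defaults 3 and 59).
#'
#' @return A list of class `segmentation_config`.
#' @export
segmentation_config <- function(speed_threshold = 30,
                                speed_threshold_unit = c("cm_s", "cm_frame"),
                                accel_threshold = 0.5,
                                likelihood_threshold = 0.9,
                                position_sd = 3,
                                shifted_gaussian_sd = 9,
                                shifted_gaussian_shift = 13,
                                suppression_offset = 100,
                                suppression_sd = 9,
                                suppression_floor = 0.05,
                                peak_min_distance = 50,
                                peak_min_height = 0.1,
                                gate_slack = 0.1,
                                hard_gates = FALSE,
                                gate_window = 50,
                                refine_rel = 0.01,
                                refine_floor = 0.3,
                                refine_noise_mult = 2.5,
                                refine_window = 200,
                                refine_smooth_window = 9,
                                smoothing_order = 3,
                                smoothing_window = 59) {
  speed_threshold_unit <- match.arg(speed_threshold_unit)
  stopifnot(speed_threshold > 0, accel_threshold > 0,
            likelihood_threshold > 0, position_sd > 0,
            peak_min_distance >= 1, suppression_sd > 0,
            shifted_gaussian_sd > 0)
  structure(as.list(environment()), class = "segmentation_config")
}

#' Region-proximity probability signal
#'
#' 1 while the hand is inside the region; outside, decays as a Gaussian of
#' the distance to the region boundary, `exp(-0.5 (d/sd)^2)`.
#'
#' @param x_cm,y_cm Hand position in cm (vectors).
#' @param region A [region_rect()], or a list of them (the signal is then
#'   the pointwise maximum over regions, i.e. proximity to the nearest).
#' @param sd Gaussian decay scale in cm.
#' @return Numeric vector in \[0, 1\].
#' @export
position_probability <- function(x_cm, y_cm, region, sd = 3) {
  if (sd <= 0) stop("`sd` must be positive", call. = FALSE)
  if (inherits(region, "region_rect")) region <- list(region)
  if (!length(region)) stop("invalid region", call. = FALSE)
  probs <- lapply(region, function(r) {
    exp(-0.5 * (rect_distance(r, x_cm, y_cm) / sd)^2)
  })
  Reduce(pmax, probs)
}

# logistic gate: ~1 where the condition holds, with 10%-of-threshold
# softness; hard 0/1 indicator when requested
soft_gate <- function(x, threshold, direction = c("above", "below"),
                      slack = 0.1, hard = FALSE) {
  direction <- match.arg(direction)
  d <- if (direction == "above") x - threshold else threshold - x
  if (hard) as.numeric(d >= 0) else stats::plogis(d / (slack * threshold))
}

# running max over a centered..one-sided window; side "future" looks at
# [i, i+w], side "past" at [i-w, i]
running_max <- function(x, w, side = c("future", "past")) {
  side <- match.arg(side)
  n <- length(x)
  if (side == "past") {
    z <- zoo::rollapply(zoo::zoo(x), width = w + 1, FUN = max,
                        align = "right", partial = TRUE)
  } else {
    z <- zoo::rollapply(zoo::zoo(x), width = w + 1, FUN = max,
                        align = "left", partial = TRUE)
  }
  as.numeric(z)
}

# Gaussian event weights anchored at movement excursions: contiguous runs
# of smoothed speed above the speed threshold mark genuine movements; for
# each such excursion the speed is followed outward to where it falls
# below `rel_cross` of the excursion's own peak, and a Gaussian (sd
# frames) is centered `shift` frames before (starts) or after (ends) that
# crossing. The relative level makes the crossing-to-boundary offset
# independent of movement amplitude, so a single calibrated `shift` works
# for slow and fast movements alike. Pointwise maximum over excursions;
# zero far from any movement.
crossing_weights <- function(smoothed_speed, threshold, kind,
                             sd = 9, shift = 13, rel_cross = 0.25) {
  n <- length(smoothed_speed)
  above <- smoothed_speed >= threshold
  if (!any(above)) return(numeric(n))
  r <- rle(above)
  run_end <- cumsum(r$lengths)
  run_start <- run_end - r$lengths + 1L
  exc <- which(r$values)
  centers <- integer(0)
  for (e in exc) {
    i0 <- run_start[e]; i1 <- run_end[e]
    lev <- rel_cross * max(smoothed_speed[i0:i1])
    if (kind == "start") {
      below <- which(smoothed_speed[seq_len(i0)] < lev)
      if (length(below)) centers <- c(centers, below[length(below)] - shift)
    } else {
      below <- which(smoothed_speed[i1:n] < lev)
      if (length(below)) centers <- c(centers, i1 - 1L + below[1L] + shift)
    }
  }
  centers <- centers[centers >= 1 & centers <= n]
  if (!length(centers)) return(numeric(n))
  idx <- seq_len(n)
  w <- numeric(n)
  for (cc in centers) {
    w <- pmax(w, exp(-0.5 * ((idx - cc) / sd)^2))
  }
  w
}

#' Combine probability signals into an objective function
#'
#' Multiplies per-frame probability signals elementwise into a single
#' objective whose peaks mark candidate movement starts or ends: the
#' product is high only where *every* source of information agrees (hand
#' in the right region, speed low, a genuine movement nearby, trustworthy
#' tracking). Any component equal to zero at a frame forces the objective
#' to zero there; an all-ones component is the identity.
#'
#' @param position_prob Region-proximity signal ([position_probability()]).
#' @param inverted_speed `1 - smoothed_speed / max(smoothed_speed)`.
#' @param speed_gate,accel_gate,likelihood_gate Threshold gates in
#'   \[0, 1\].
#' @param shifted_gaussian Optional Gaussian event weights
#'   (crossing-anchored); omit with `NULL`.
#' @param kind `"start"` or `"end"` (recorded, not interpreted).
#' @return An object of class `objective_signals`: list with the
#'   components and their product `objective`.
#' @export
build_objective <- function(position_prob, inverted_speed, speed_gate,
                            accel_gate, likelihood_gate,
                            shifted_gaussian = NULL,
                            kind = c("start", "end")) {
  kind <- match.arg(kind)
  comps <- list(position_prob = position_prob,
                inverted_speed = inverted_speed,
                speed_gate = speed_gate, accel_gate = accel_gate,
                likelihood_gate = likelihood_gate)
  if (!is.null(shifted_gaussian)) comps$shifted_gaussian <- shifted_gaussian
  n <- unique(vapply(comps, length, integer(1)))
  if (length(n) != 1L) {
    stop("all component signals must have the same length", call. = FALSE)
  }
  obj <- Reduce(`*`, comps)
  structure(c(comps, list(objective = obj, kind = kind)),
            class = "objective_signals")
}

#' Standard start/end objective for a trial
#'
#' Builds the full objective function for detecting movement starts or
#' ends of one phase from a calibrated track: region proximity, inverted
#' smoothed speed, speed/acceleration/likelihood threshold gates, and
#' Gaussian weights anchored at speed-threshold crossings.
#'
#' @param track An interpolated [keypoint_track()].
#' @param kin A [kinematic_series()] for the track.
#' @param region Region(s) the hand must occupy at the event
#'   ([position_probability()]).
#' @param kind `"start"` or `"end"`.
#' @param config A [segmentation_config()].
#' @return An `objective_signals` object (see [build_objective()]).
#' @export
trial_objective <- function(track, kin, region, kind = c("start", "end"),
                            config = segmentation_config()) {
  kind <- match.arg(kind)
  sm_cms <- speed_to_cm_s(kin$smoothed_speed, track$pixel_scale, track$fps)
  thr_cms <- if (config$speed_threshold_unit == "cm_s") {
    config$speed_threshold
  } else {
    config$speed_threshold * track$fps
  }
  acc_cmf2 <- kin$acceleration * track$pixel_scale

  pos <- position_probability(track$x * track$pixel_scale,
                              track$y * track$pixel_scale,
                              region, sd = config$position_sd)
  mx <- max(sm_cms)
  inv_speed <- if (mx > 0) 1 - sm_cms / mx else rep(1, length(sm_cms))
  side <- if (kind == "start") "future" else "past"
  sgate <- soft_gate(running_max(sm_cms, config$gate_window, side),
                     thr_cms, "above", config$gate_slack, config$hard_gates)
  agate <- soft_gate(abs(acc_cmf2), config$accel_threshold, "below",
                     config$gate_slack, config$hard_gates)
  lgate <- as.numeric(track$likelihood >= config$likelihood_threshold)
  sg <- crossing_weights(sm_cms, thr_cms, kind,
                         sd = config$shifted_gaussian_sd,
                         shift = config$shifted_gaussian_shift)
  build_objective(pos, inv_speed, sgate, agate, lgate, sg, kind = kind)
}

#' Mutual suppression of start and end objectives
#'
#' Movement starts and ends come in pairs roughly `suppression_offset`
#' frames apart, so activity in one objective that has no plausible
#' counterpart in the other is down-weighted: the end objective is
#' multiplied by Gaussian windows (SD `suppression_sd`) centered
#' `suppression_offset` frames *after* each provisional start, and the
#' start objective by windows the same distance *before* each provisional
#' end, both on a `suppression_floor` baseline. With no provisional events
#' the objectives are returned unchanged.
#'
#' @param start_obj,end_obj Numeric objective vectors (equal length).
#' @param starts,ends Provisional event frames (either may be `NULL`).
#' @param config A [segmentation_config()].
#' @return List with re-weighted `start` and `end` objectives.
#' @export
apply_mutual_suppression <- function(start_obj, end_obj,
                                     starts = NULL, ends = NULL,
                                     config = segmentation_config()) {
  n <- length(start_obj)
  stopifnot(length(end_obj) == n)
  win <- function(centers) {
    if (is.null(centers) || !length(centers)) return(NULL)
    idx <- seq_len(n)
    w <- numeric(n)
    for (cc in centers) {
      w <- pmax(w, exp(-0.5 * ((idx - cc) / config$suppression_sd)^2))
    }
    config$suppression_floor + (1 - config$suppression_floor) * w
  }
  w_end <- win(if (length(starts)) starts + config$suppression_offset)
  w_start <- win(if (length(ends)) ends - config$suppression_offset)
  list(
    start = if (is.null(w_start)) start_obj else start_obj * w_start,
    end = if (is.null(w_end)) end_obj else end_obj * w_end
  )
}

#' Detect events as constrained peaks of an objective
#'
#' Finds local maxima of the objective (plateaus count once, at their
#' first frame), discards those below `min_height`, and greedily keeps
#' peaks in descending height -- ties broken in favour of the earlier
#' frame -- subject to a pairwise separation of at least `min_distance`
#' frames.
#'
#' @param objective Numeric vector (finite).
#' @param min_distance Minimum frames between kept events (default 50).
#' @param min_height Minimum objective value of a kept event.
#' @return Sorted integer vector of event frames (possibly empty).
#' @export
detect_events <- function(objective, min_distance = 50, min_height = 0.1) {
  stopifnot(all(is.finite(objective)))
  n <- length(objective)
  if (n < 3L || all(objective <= 0)) return(integer(0))
  # plateau-aware local maxima: first index of each run that exceeds both
  # neighbouring runs
  r <- rle(objective)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  k <- length(r$values)
  is_peak <- vapply(seq_len(k), function(i) {
    left <- if (i == 1L) -Inf else r$values[i - 1L]
    right <- if (i == k) -Inf else r$values[i + 1L]
    r$values[i] > left && r$values[i] > right
  }, logical(1))
  cand <- starts[is_peak]
  cand <- cand[objective[cand] >= min_height]
  if (!length(cand)) return(integer(0))
  ord <- order(-objective[cand], cand)
  kept <- integer(0)
  for (i in cand[ord]) {
    if (!length(kept) || all(abs(kept - i) >= min_distance)) {
      kept <- c(kept, i)
    }
  }
  sort(kept)
}

# Snap a coarse event to the movement boundary on a lightly smoothed
# speed signal. The movement leg adjacent to the event is located as the
# first sustained excursion of speed above an adaptive resting level
# (after the event for starts, before it for ends); the boundary is then
# the last (first) frame below a threshold tied to that leg's own peak.
refine_boundary <- function(event, s_light_cms, type, config) {
  n <- length(s_light_cms)
  noise_level <- stats::quantile(s_light_cms, 0.10, names = FALSE)
  base <- max(config$refine_floor, config$refine_noise_mult * noise_level)
  sustain <- 5L
  above <- s_light_cms >= base
  sustained_at <- function(i) {
    idx <- i:min(n, i + sustain - 1L)
    all(above[idx])
  }
  if (type == "start") {
    lo <- max(1L, event - 10L)
    hi <- min(n - sustain, event + config$refine_window)
    a0 <- NA_integer_
    for (i in lo:hi) if (above[i] && sustained_at(i)) { a0 <- i; break }
    if (is.na(a0)) return(event)
    drop_i <- a0
    while (drop_i < n && above[drop_i]) drop_i <- drop_i + 1L
    peak <- max(s_light_cms[a0:drop_i])
    thr <- max(config$refine_rel * peak, base)
    below <- which(s_light_cms[seq_len(a0)] < thr)
    if (!length(below)) return(event)
    below[length(below)] # last resting frame before the leg
  } else {
    hi <- min(n, event + 10L)
    lo <- max(1L + sustain, event - config$refine_window)
    b0 <- NA_integer_
    for (i in hi:lo) {
      if (above[i] && all(above[max(1L, i - sustain + 1L):i])) { b0 <- i; break }
    }
    if (is.na(b0)) return(event)
    rise_i <- b0
    while (rise_i > 1L && above[rise_i]) rise_i <- rise_i - 1L
    peak <- max(s_light_cms[rise_i:b0])
    thr <- max(config$refine_rel * peak, base)
    seg <- s_light_cms[b0:n]
    below <- which(seg < thr)
    if (!length(below)) return(event)
    b0 - 1L + below[1L] # first resting frame after the leg
  }
}

#' Segment one trial into reach and transport movements
#'
#' Runs the full objective-function machinery on one trial, separately for
#' reach movements (starting at the start key or on the placing pad,
#' ending on the picking pad) and transport movements (picking pad to
#' placing pad). For each phase: provisional starts are detected from the
#' unsuppressed start objective, ends from the end objective under mutual
#' suppression by those starts, and starts are then re-detected under
#' suppression by the ends. Detected events are snapped to movement
#' boundaries on a lightly smoothed speed signal. A phase passes only if
#' exactly `search_size` starts and ends are found and they interleave;
#' otherwise the phase is discarded with a machine-readable reason
#' (`"count-mismatch"` or `"pairing-error"`). Reach and transport keep
#' separate pass/fail status, so a trial can contribute to one analysis
#' but not the other.
#'
#' @param track A [keypoint_track()] (interpolated internally if needed).
#' @param spec Trial metadata row with at least `search_size`; optionally
#'   `trial_id`.
#' @param config A [segmentation_config()].
#' @param layout A [workspace_layout()].
#' @return A list of class `trial_segmentation`: `segments` (tibble with
#'   `trial_id`, `index`, `phase`, `start_frame`, `end_frame`,
#'   `duration_ms`, only for phases that passed), `reach_ok`,
#'   `transport_ok`, `reach_reason`, `transport_reason`.
#' @export
segment_trial <- function(track, spec, config = segmentation_config(),
                          layout = workspace_layout()) {
  stopifnot(inherits(track, "keypoint_track"))
  k <- as.integer(spec$search_size)
  trial_id <- if (!is.null(spec$trial_id)) as.character(spec$trial_id) else NA_character_
  track <- interpolate_low_confidence(track)
  n <- length(track$x)
  fail_all <- function(reason) {
    structure(list(
      segments = empty_segments(), reach_ok = FALSE, transport_ok = FALSE,
      reach_reason = reason, transport_reason = reason
    ), class = "trial_segmentation")
  }
  if (n < config$smoothing_window + 2L) return(fail_all("track-too-short"))
  kin <- kinematic_series(track, config$smoothing_order,
                          config$smoothing_window)
  s_light <- speed_to_cm_s(
    smooth_series(kin$speed, order = 2,
                  window = config$refine_smooth_window),
    track$pixel_scale, track$fps
  )

  phase_regions <- list(
    reach = list(start = list(layout$start_key, layout$placing_pad),
                 end = layout$picking_pad),
    transport = list(start = layout$picking_pad,
                     end = layout$placing_pad)
  )

  res <- list()
  for (phase in names(phase_regions)) {
    rg <- phase_regions[[phase]]
    so <- trial_objective(track, kin, rg$start, "start", config)$objective
    eo <- trial_objective(track, kin, rg$end, "end", config)$objective
    starts0 <- detect_events(so, config$peak_min_distance,
                             config$peak_min_height)
    sup1 <- apply_mutual_suppression(so, eo, starts = starts0,
                                     config = config)
    ends <- detect_events(sup1$end, config$peak_min_distance,
                          config$peak_min_height)
    sup2 <- apply_mutual_suppression(so, eo, ends = ends, config = config)
    starts <- detect_events(sup2$start, config$peak_min_distance,
                            config$peak_min_height)

    ok <- length(starts) == k && length(ends) == k
    reason <- if (ok) NA_character_ else "count-mismatch"
    segs <- NULL
    if (ok) {
      starts_r <- vapply(starts, refine_boundary, numeric(1),
                         s_light_cms = s_light, type = "start", config = config)
      ends_r <- vapply(ends, refine_boundary, numeric(1),
                       s_light_cms = s_light, type = "end", config = config)
      inter <- all(starts_r < ends_r) &&
        (k == 1L || all(ends_r[-k] < starts_r[-1L]))
      if (!inter) {
        ok <- FALSE
        reason <- "pairing-error"
      } else {
        segs <- tibble::tibble(
          trial_id = trial_id, index = seq_len(k), phase = phase,
          start_frame = as.integer(starts_r), end_frame = as.integer(ends_r),
          duration_ms = (ends_r - starts_r) * 1000 / track$fps
        )
      }
    }
    res[[phase]] <- list(ok = ok, reason = reason, segs = segs)
  }

  segments <- dplyr::bind_rows(res$reach$segs, res$transport$segs)
  if (nrow(segments) > 0L) {
    segments <- dplyr::arrange(segments, .data$start_frame)
  } else {
    segments <- empty_segments()
  }
  structure(list(
    segments = segments,
    reach_ok = res$reach$ok, transport_ok = res$transport$ok,
    reach_reason = res$reach$reason, transport_reason = res$transport$reason
  ), class = "trial_segmentation")
}

empty_segments <- function() {
  tibble::tibble(trial_id = character(0), index = integer(0),
                 phase = character(0), start_frame = integer(0),
                 end_frame = integer(0), duration_ms = numeric(0))
}

#' Participant-level quality control
#'
#' A participant is excluded when strictly more than one third of their
#' trials were removed.
#'
#' @param removed Logical vector, one element per trial (`TRUE` =
#'   removed).
#' @return `"keep"` or `"exclude"`.
#' @examples
#' qc_participant(rep(c(TRUE, FALSE), c(27, 54)))  # exactly 1/3: "keep"
#' @export
qc_participant <- function(removed) {
  if (!length(removed)) stop("no trial statuses supplied", call. = FALSE)
  removed <- as.logical(removed)
  if (anyNA(removed)) stop("trial statuses must be TRUE/FALSE", call. = FALSE)
  if (mean(removed) > 1 / 3) "exclude" else "keep"
}
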