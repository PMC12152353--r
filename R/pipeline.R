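#' Segment every trial of a cohort
#'
#' Runs [segment_trial()] over all tracks of a cohort and collects
#' segments and per-trial pass/fail status for the reach and transport
#' analyses.
#'
#' @param cohort A [generate_cohort()] result with tracks.
#' @param config A [segmentation_config()].
#' @return A list with `segments` (tibble over all passing phases) and
#'   `status` (tibble with `participant_id`, `trial_id`, `reach_ok`,
#'   `transport_ok`, `reach_reason`, `transport_reason`).
#' @export
segment_cohort <- function(cohort, config = segmentation_config()) {
  ids <- names(cohort$tracks)
  if (!length(ids)) stop("cohort has no tracks", call. = FALSE)
  meta <- cohort$trials
  seg_list <- vector("list", length(ids))
  status <- vector("list", length(ids))
  for (i in seq_along(ids)) {
    id <- ids[i]
    spec <- meta[meta$trial_id == id, ]
    res <- segment_trial(cohort$tracks[[id]], spec, config, cohort$layout)
    seg_list[[i]] <- res$segments
    status[[i]] <- tibble::tibble(
      participant_id = spec$participant_id, trial_id = id,
      reach_ok = res$reach_ok, transport_ok = res$transport_ok,
      reach_reason = res$reach_reason,
      transport_reason = res$transport_reason
    )
  }
  list(segments = dplyr::bind_rows(seg_list),
       status = dplyr::bind_rows(status))
}

#' Dependent variables for a segmented cohort
#'
#' Computes per-movement kinematic summaries ([measure_trial()]) for all
#' segmented trials and joins the trial metadata.
#'
#' @param cohort A [generate_cohort()] result with tracks.
#' @param segmentation A [segment_cohort()] result.
#' @return A tibble with one row per movement: trial metadata columns
#'   plus `phase`, `index`, `duration_ms`, `avg_speed_cm_s`,
#'   `peak_speed_cm_s`, `deceleration_pct`, `distance_cm`, `path_ratio`,
#'   `onset_ms` (first reach rows only).
#' @export
measure_cohort <- function(cohort, segmentation) {
  segs <- segmentation$segments
  if (nrow(segs) == 0L) return(tibble::tibble())
  ids <- unique(segs$trial_id)
  meta <- cohort$trials
  rows <- lapply(ids, function(id) {
    spec <- meta[meta$trial_id == id, ]
    fake <- list(segments = segs[segs$trial_id == id, ])
    measure_trial(cohort$tracks[[id]], fake, spec$audio_end_time_ms)
  })
  out <- dplyr::bind_rows(rows)
  dplyr::left_join(
    out,
    meta[, c("trial_id", "participant_id", "block", "instruction",
             "target_color", "search_size")],
    by = "trial_id"
  )
}

#' Participant exclusion over a segmented cohort
#'
#' Applies the participant-level quality criterion ([qc_participant()]) to
#' one analysis (reach or transport): participants with more than a third
#' of their trials removed are excluded.
#'
#' @param status The `status` tibble from [segment_cohort()].
#' @param phase `"reach"` or `"transport"`.
#' @return Tibble with `participant_id`, `n_removed`, `n_trials`,
#'   `decision`.
#' @export
qc_cohort <- function(status, phase = c("reach", "transport")) {
  phase <- match.arg(phase)
  okcol <- paste0(phase, "_ok")
  status |>
    dplyr::group_by(.data$participant_id) |>
    dplyr::summarise(
      n_removed = sum(!.data[[okcol]]),
      n_trials = dplyr::n(),
      decision = qc_participant(!.data[[okcol]]),
      .groups = "drop"
    )
}
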