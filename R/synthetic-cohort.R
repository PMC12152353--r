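#' Simulate a cohort of participants
#'
#' Generates a full synthetic dataset: one balanced trial schedule per
#' participant, participant-level effect offsets, and (optionally) the
#' frame-by-frame hand tracks with ground truth for every trial. Scene
#' images are not stored; they are rendered on demand from the per-trial
#' brick inventory with [cohort_scene_pair()], which keeps even large
#' cohorts in memory.
#'
#' The whole dataset is a deterministic function of `params$seed`.
#'
#' @param params A [cohort_params()].
#' @param layout A [workspace_layout()].
#' @param tracks If `FALSE`, only schedules and metadata are generated
#'   (fast; sufficient for design-level checks).
#'
#' @return A list of class `forage_cohort` with elements:
#'   * `trials`: tibble of trial metadata (`participant_id`, `trial_id`,
#'     `block`, `trial_index`, `instruction`, `target_color`,
#'     `search_size`, `audio_end_time_ms`, and -- when tracks are
#'     generated -- `artifact`, `first_target_size`, `onset_true_ms`);
#'   * `tracks`: named list of [keypoint_track()]s keyed by `trial_id`;
#'   * `ground_truth`: named list of per-trial ground truth;
#'   * `params`, `layout`.
#' @examples
#' p <- cohort_params(n_participants = 2, trials_per_participant = 9)
#' coh <- generate_cohort(p, tracks = FALSE)
#' nrow(coh$trials)  # 18
#' @export
generate_cohort <- function(params = cohort_params(),
                            layout = workspace_layout(),
                            tracks = TRUE) {
  stopifnot(inherits(params, "cohort_params"))
  old <- if (exists(".Random.seed", envir = globalenv())) {
    get(".Random.seed", envir = globalenv())
  } else NULL
  on.exit({
    if (!is.null(old)) assign(".Random.seed", old, envir = globalenv())
  }, add = TRUE)
  set.seed(params$seed)

  n_blocks <- params$trials_per_participant %/% 9L
  pids <- sprintf("P%02d", seq_len(params$n_participants))

  meta <- list(); trk <- list(); gt <- list()
  for (p in seq_along(pids)) {
    sched <- generate_schedule(
      seed = params$seed + 7919L * p, n_blocks = n_blocks,
      audio_ms = params$audio_ms
    )
    sched$participant_id <- pids[p]
    sched$trial_id <- sprintf("%s_T%03d", pids[p], sched$trial_index)
    effects <- list(
      decel = stats::rnorm(1, 0, params$sd_f_participant),
      decel_instr = stats::setNames(
        stats::rnorm(3, 0, params$sd_f_instruction), INSTRUCTIONS),
      onset_ms = stats::rnorm(1, 0, 60),
      logit_large = stats::rnorm(1, 0, params$sd_logit_large)
    )
    if (tracks) {
      sched$artifact <- NA
      sched$first_target_size <- NA_character_
      sched$onset_true_ms <- NA_real_
      for (i in seq_len(nrow(sched))) {
        sim <- generate_trial_trajectory(sched[i, ], layout, params, effects)
        id <- sched$trial_id[i]
        trk[[id]] <- sim$track
        gt[[id]] <- sim$ground_truth
        sched$artifact[i] <- sim$ground_truth$artifact
        sched$first_target_size[i] <- sim$ground_truth$first_target_size
        sched$onset_true_ms[i] <- sim$ground_truth$onset_ms
      }
    }
    meta[[p]] <- sched
  }
  structure(
    list(trials = dplyr::bind_rows(meta), tracks = trk, ground_truth = gt,
         params = params, layout = layout),
    class = "forage_cohort"
  )
}

#' @export
print.forage_cohort <- function(x, ...) {
  cat(sprintf(
    "<forage_cohort> %d participants x %d trials (%d tracks generated)\n",
    x$params$n_participants, x$params$trials_per_participant,
    length(x$tracks)
  ))
  invisible(x)
}

#' Scene pair for one cohort trial
#'
#' Renders the start/end scene images of a trial from its stored brick
#' inventory (see [generate_scene_pair()]).
#'
#' @param cohort A [generate_cohort()] result with tracks.
#' @param trial_id Trial identifier (row of `cohort$trials`).
#' @return A list with RGB arrays `start` and `end`.
#' @export
cohort_scene_pair <- function(cohort, trial_id) {
  g <- cohort$ground_truth[[trial_id]]
  if (is.null(g)) stop("unknown trial_id: ", trial_id, call. = FALSE)
  # piled deposits overlap by design; the overlap warning is only useful
  # for hand-built scenes
  suppressWarnings(generate_scene_pair(
    cohort$layout,
    placed_positions = g$placed,
    picked_positions = g$picked[, c("x", "y", "size", "color")],
    seed = cohort$params$seed + sum(utf8ToInt(trial_id)),
    static = g$static[, c("x", "y", "size", "color")]
  ))
}

#' Write a cohort to disk
#'
#' Exports a generated cohort as plain files: per-trial keypoint CSVs
#' (see [write_keypoint_track()]), a metadata CSV, per-trial ground-truth
#' JSON sidecars, and optionally the scene-image pairs as PNG.
#'
#' @param cohort A [generate_cohort()] result.
#' @param dir Output directory (created if missing).
#' @param scenes Also render and write scene PNGs (slower).
#' @return `dir`, invisibly.
#' @export
write_cohort <- function(cohort, dir, scenes = FALSE) {
  if (!requireNamespace("jsonlite", quietly = TRUE)) {
    stop("writing cohorts requires the 'jsonlite' package", call. = FALSE)
  }
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  utils::write.csv(cohort$trials, file.path(dir, "trials.csv"),
                   row.names = FALSE)
  for (id in names(cohort$tracks)) {
    write_keypoint_track(cohort$tracks[[id]],
                         file.path(dir, paste0(id, "_track.csv")))
    jsonlite::write_json(cohort$ground_truth[[id]],
                         file.path(dir, paste0(id, "_truth.json")),
                         auto_unbox = TRUE, digits = NA, na = "null")
    if (scenes) {
      pair <- cohort_scene_pair(cohort, id)
      write_scene_png(pair$start, file.path(dir, paste0(id, "_start.png")))
      write_scene_png(pair$end, file.path(dir, paste0(id, "_end.png")))
    }
  }
  invisible(dir)
}
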