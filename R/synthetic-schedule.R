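INSTRUCTIONS <- c("collect", "sort", "pile")
TARGET_COLORS <- c("blue", "red", "yellow")
SEARCH_SIZES <- c(3L, 4L, 5L)

#' Generate a balanced trial schedule
#'
#' Builds the trial list for one session. Every block holds nine trials:
#' each placing instruction (collect, sort, pile) and each target color
#' (blue, red, yellow) occurs exactly three times per block, in random
#' order. Search sizes (3, 4, 5) are random but balanced so that over any
#' three consecutive blocks -- and hence over the nine-block main
#' experiment -- every instruction x search-size x color triple occurs
#' equally often (three times in nine blocks).
#'
#' @param seed Integer seed for the schedule randomisation.
#' @param n_blocks Number of nine-trial blocks (default 9, i.e. the
#'   81-trial main experiment).
#' @param audio_ms Mean duration of the spoken trial instruction in ms
#'   (the audio ends and the response interval starts at
#'   `audio_end_time_ms`); jittered uniformly by +/- 150 ms per trial.
#'
#' @return A [tibble::tibble] with one row per trial: `block`,
#'   `trial_index`, `instruction`, `target_color`, `search_size`,
#'   `audio_end_time_ms`.
#' @examples
#' sched <- generate_schedule(seed = 1, n_blocks = 9)
#' nrow(sched)            # 81
#' table(sched$instruction)
#' @export
generate_schedule <- function(seed = 1L, n_blocks = 9L, audio_ms = 2000) {
  if (!is.numeric(n_blocks) || length(n_blocks) != 1L || n_blocks < 1 ||
      n_blocks != round(n_blocks)) {
    stop("`n_blocks` must be a positive integer", call. = FALSE)
  }
  n_blocks <- as.integer(n_blocks)
  # seed locally, restoring the caller's RNG state on exit
  old <- if (exists(".Random.seed", envir = globalenv())) {
    get(".Random.seed", envir = globalenv())
  } else NULL
  on.exit({
    if (!is.null(old)) assign(".Random.seed", old, envir = globalenv())
  }, add = TRUE)
  set.seed(seed)

  # each block contains every (instruction x color) pair exactly once,
  # which yields the 3x-per-block balance of both factors
  pairs <- expand.grid(instruction = INSTRUCTIONS, target_color = TARGET_COLORS,
                       KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  # search sizes per pair: independent random permutations of {3,4,5},
  # consumed across blocks -> exact triple balance every 3 blocks
  n_cycles <- ceiling(n_blocks / 3)
  size_seq <- lapply(seq_len(nrow(pairs)), function(i) {
    unlist(lapply(seq_len(n_cycles), function(j) sample(SEARCH_SIZES)))
  })

  blocks <- lapply(seq_len(n_blocks), function(b) {
    ord <- sample.int(nrow(pairs))
    df <- pairs[ord, , drop = FALSE]
    df$search_size <- vapply(ord, function(i) size_seq[[i]][b], integer(1))
    df$block <- b
    df
  })
  out <- do.call(rbind, blocks)
  out$trial_index <- seq_len(nrow(out))
  out$audio_end_time_ms <- audio_ms + stats::runif(nrow(out), -150, 150)
  tibble::as_tibble(out[, c("block", "trial_index", "instruction",
                            "target_color", "search_size",
                            "audio_end_time_ms")])
}

#' Cohort simulation parameters
#'
#' Collects every tunable of the synthetic cohort generator. The defaults
#' encode the study conditions the generator emulates: 24 participants with
#' 81 trials each; transport deceleration fractions of 0.510 (collect),
#' 0.535 (sort) and 0.547 (pile) with symmetric (0.50) reach profiles;
#' first-target large-size probabilities of 0.844 / 0.819 / 0.888 for
#' collect / sort / pile; target positions biased toward the near-left
#' quadrant of the picking pad; a mean movement onset of 562.6 ms after
#' audio offset; ~500 ms movement legs; 300 ms grasp/place dwells; mild
#' autocorrelated tracking jitter and 1% likelihood dropouts.
#'
#' @param n_participants Number of simulated participants.
#' @param trials_per_participant Trials per participant; must be a
#'   multiple of 9 (whole blocks).
#' @param deceleration_fraction Named numeric: planted transport
#'   deceleration fraction (proportion of leg duration after peak speed)
#'   per instruction.
#' @param reach_deceleration_fraction Deceleration fraction of reach legs
#'   (identical across instructions by default).
#' @param p_large_first Named numeric: probability that the first selected
#'   target is a large brick, per instruction.
#' @param quadrant_weights Length-4 probability vector (quadrants 1..4 =
#'   far-left, far-right, near-left, near-right) used to place targets on
#'   the picking pad; must sum to 1.
#' @param noise_sd_px Stationary SD of the tracking jitter in pixels.
#' @param noise_ar Lag-1 autocorrelation of the jitter (markerless
#'   trackers drift smoothly rather than flickering).
#' @param p_likelihood_dropout Per-frame probability of a likelihood
#'   dropout (likelihood drawn uniform on \[0, 0.7), position perturbed
#'   with 10x noise so interpolation is consequential).
#' @param dwell_ms Grasp/place dwell duration in ms.
#' @param leg_duration_ms,leg_duration_sd_ms Mean and SD of a movement
#'   leg's duration in ms (duration is amplitude-invariant, so peak speed
#'   scales with distance).
#' @param onset_mean_ms,onset_sd_ms First-movement onset distribution
#'   (time from audio offset to first reach start), truncated at 150 ms.
#' @param curvature,curvature_sd Mean and SD of the perpendicular bulge of
#'   a leg's path, as a fraction of the straight-line distance (sagitta /
#'   chord; 0 = straight). The default 0.2 yields gently curved reaches
#'   whose path ratios land near 1.1, typical of unconstrained natural
#'   reaches.
#' @param sd_f_participant SD of the participant-level offset added to all
#'   deceleration fractions.
#' @param sd_f_instruction SD of the participant x instruction offset.
#' @param sd_f_trial SD of the leg-level deceleration-fraction noise.
#' @param sd_logit_large SD of the participant-level offset on the logit
#'   of `p_large_first`.
#' @param p_artifact Per-trial probability of a dropped-object artifact: a
#'   transport that merges into the subsequent reach without a stop, which
#'   makes the trial unsegmentable.
#' @param audio_ms Mean audio-instruction duration in ms.
#' @param seed Integer seed; the whole cohort is a deterministic function
#'   of it.
#'
#' @return A list of class `cohort_params`.
#' @export
cohort_params <- function(n_participants = 24L,
                          trials_per_participant = 81L,
                          deceleration_fraction = c(collect = 0.510,
                                                    sort = 0.535,
                                                    pile = 0.547),
                          reach_deceleration_fraction = 0.50,
                          p_large_first = c(collect = 0.844,
                                            sort = 0.819,
                                            pile = 0.888),
                          quadrant_weights = c(0.24, 0.19, 0.33, 0.24),
                          noise_sd_px = 1,
                          noise_ar = 0.9,
                          p_likelihood_dropout = 0.01,
                          dwell_ms = 300,
                          leg_duration_ms = 500,
                          leg_duration_sd_ms = 20,
                          onset_mean_ms = 562.6,
                          onset_sd_ms = 120,
                          curvature = 0.2,
                          curvature_sd = 0.04,
                          sd_f_participant = 0.012,
                          sd_f_instruction = 0.005,
                          sd_f_trial = 0.025,
                          sd_logit_large = 0.3,
                          p_artifact = 0,
                          audio_ms = 2000,
                          seed = 1L) {
  stopifnot(n_participants >= 1, trials_per_participant >= 9)
  if (trials_per_participant %% 9 != 0) {
    stop("`trials_per_participant` must be a multiple of 9 (whole blocks)",
         call. = FALSE)
  }
  if (!setequal(names(deceleration_fraction), INSTRUCTIONS) ||
      !setequal(names(p_large_first), INSTRUCTIONS)) {
    stop("per-instruction parameters must be named collect/sort/pile",
         call. = FALSE)
  }
  probs <- c(p_large_first, p_likelihood_dropout, p_artifact)
  if (any(probs < 0 | probs > 1)) {
    stop("probabilities must lie in [0, 1]", call. = FALSE)
  }
  if (length(quadrant_weights) != 4L || any(quadrant_weights < 0) ||
      abs(sum(quadrant_weights) - 1) > 1e-8) {
    stop("`quadrant_weights` must be 4 non-negative values summing to 1",
         call. = FALSE)
  }
  if (any(deceleration_fraction <= 0 | deceleration_fraction >= 1) ||
      reach_deceleration_fraction <= 0 || reach_deceleration_fraction >= 1) {
    stop("deceleration fractions must lie strictly in (0, 1)", call. = FALSE)
  }
  structure(
    list(n_participants = as.integer(n_participants),
         trials_per_participant = as.integer(trials_per_participant),
         deceleration_fraction = deceleration_fraction[INSTRUCTIONS],
         reach_deceleration_fraction = reach_deceleration_fraction,
         p_large_first = p_large_first[INSTRUCTIONS],
         quadrant_weights = quadrant_weights,
         noise_sd_px = noise_sd_px, noise_ar = noise_ar,
         p_likelihood_dropout = p_likelihood_dropout,
         dwell_ms = dwell_ms,
         leg_duration_ms = leg_duration_ms,
         leg_duration_sd_ms = leg_duration_sd_ms,
         onset_mean_ms = onset_mean_ms, onset_sd_ms = onset_sd_ms,
         curvature = curvature, curvature_sd = curvature_sd,
         sd_f_participant = sd_f_participant,
         sd_f_instruction = sd_f_instruction,
         sd_f_trial = sd_f_trial,
         sd_logit_large = sd_logit_large,
         p_artifact = p_artifact,
         audio_ms = audio_ms,
         seed = as.integer(seed)),
    class = "cohort_params"
  )
}
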