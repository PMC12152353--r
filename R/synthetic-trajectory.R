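# Minimum-jerk position profile s(tau) on [0,1]: smooth point-to-point
# reach with zero boundary velocity/acceleration; speed peaks at tau = 0.5.
mj_pos <- function(tau) 10 * tau^3 - 15 * tau^4 + 6 * tau^5

#' Asymmetric minimum-jerk distance profile
#'
#' Fraction of the total path length covered at normalised time `u` for a
#' movement leg whose deceleration phase (time after peak speed) occupies
#' fraction `f` of the leg duration. Each half of the minimum-jerk speed
#' profile is dilated linearly in time (accelerative half to `[0, 1-f]`,
#' decelerative half to `[1-f, 1]`) with amplitudes matched at the peak, so
#' the speed is continuous, vanishes at both ends and attains its unique
#' maximum exactly at `u = 1 - f`. `f = 0.5` recovers the symmetric
#' minimum-jerk profile.
#'
#' @param u Normalised time in \[0, 1\] (vectorised).
#' @param f Deceleration fraction in (0, 1).
#' @return Fraction of path length covered, in \[0, 1\].
#' @examples
#' leg_profile(0.5, 0.5)   # 0.5: symmetric profile, half way at half time
#' @export
leg_profile <- function(u, f = 0.5) {
  stopifnot(f > 0, f < 1)
  us <- 1 - f # time fraction at peak speed
  out <- numeric(length(u))
  a <- u <= us
  out[a] <- 2 * us * mj_pos(0.5 * u[a] / us)
  out[!a] <- us + 2 * (1 - us) * (mj_pos(0.5 + 0.5 * (u[!a] - us) / (1 - us)) - 0.5)
  pmin(pmax(out, 0), 1)
}

# Quadratic Bezier through A and B with perpendicular bulge; `sagitta` is
# the mid-path offset as a fraction of the chord (signed). Returns a
# function mapping normalised arc length in [0,1] to xy positions.
bezier_arclength_curve <- function(A, B, sagitta = 0, n_ref = 400) {
  chord <- sqrt(sum((B - A)^2))
  if (chord < 1e-9) stop("degenerate leg: coincident endpoints", call. = FALSE)
  perp <- c(-(B[2] - A[2]), B[1] - A[1]) / chord
  C <- (A + B) / 2 + perp * (2 * sagitta * chord)
  tt <- seq(0, 1, length.out = n_ref)
  px <- (1 - tt)^2 * A[1] + 2 * tt * (1 - tt) * C[1] + tt^2 * B[1]
  py <- (1 - tt)^2 * A[2] + 2 * tt * (1 - tt) * C[2] + tt^2 * B[2]
  seglen <- c(0, sqrt(diff(px)^2 + diff(py)^2))
  cum <- cumsum(seglen)
  total <- cum[n_ref]
  list(
    length = total,
    at = function(s_frac) {
      s <- pmin(pmax(s_frac, 0), 1) * total
      cbind(stats::approx(cum, px, xout = s, ties = "ordered")$y,
            stats::approx(cum, py, xout = s, ties = "ordered")$y)
    }
  )
}

# One movement leg sampled on the frame grid. Returns positions for frames
# 1..n_frames (position at frame i corresponds to time (i-1)/fps after leg
# onset); the final sample sits exactly at B.
make_leg <- function(A, B, n_frames, f = 0.5, sagitta = 0) {
  curve <- bezier_arclength_curve(A, B, sagitta)
  u <- seq(0, 1, length.out = n_frames + 1)[-1] # frame times after onset
  frac <- leg_profile(u, f)
  list(xy = curve$at(frac), length = curve$length)
}

#' Simulate one pick-and-place trial
#'
#' Synthesises the hand trajectory of a single trial as tracked by the
#' overhead camera: the hand rests on the start key during the audio
#' instruction, starts the first reach after a planted onset delay, then
#' alternates reach legs (to a target on the picking pad) and transport
#' legs (to a deposit location on the placing pad) with grasp/place dwells
#' in between, and finally returns to the start key. Legs follow
#' asymmetric minimum-jerk profiles ([leg_profile()]) along gently curved
#' paths; transport legs carry the instruction-specific planted
#' deceleration fraction. Tracking noise, likelihood dropouts and
#' (optionally) dropped-object artifacts are added per
#' [cohort_params()].
#'
#' @param spec One trial row as returned by [generate_schedule()] (fields
#'   `instruction`, `target_color`, `search_size`, `audio_end_time_ms`).
#' @param layout A [workspace_layout()].
#' @param params A [cohort_params()].
#' @param effects Optional participant-level effects, a list with numeric
#'   elements `decel` (offset to all deceleration fractions),
#'   `decel_instr` (named per-instruction offsets), `onset_ms`,
#'   `logit_large`. Defaults to no offsets.
#'
#' @return A list with elements `track` (a [keypoint_track()], pixel
#'   coordinates) and `ground_truth` (see Details).
#'
#' @details The ground truth is a list with: `segments`, a tibble of true
#'   movement boundaries (`phase`, `index`, `start_frame`, `end_frame`,
#'   1-based frames, `decel_fraction`, `distance_cm`); `onset_ms`;
#'   `first_target_size`; `target_quadrants`; `artifact`; and the brick
#'   inventory used for scene rendering (`picked`, `placed`, `static`
#'   tibbles of positions, sizes and colors). In artifact trials the
#'   merged transport+reach pair is recorded as a single `phase =
#'   "artifact"` segment.
#' @export
generate_trial_trajectory <- function(spec, layout = workspace_layout(),
                                      params = cohort_params(),
                                      effects = NULL) {
  fps <- 200
  ms_per_frame <- 1000 / fps
  instr <- as.character(spec$instruction)
  k <- as.integer(spec$search_size)
  if (is.null(effects)) {
    effects <- list(decel = 0,
                    decel_instr = c(collect = 0, sort = 0, pile = 0),
                    onset_ms = 0, logit_large = 0)
  }

  pick <- layout$picking_pad
  place <- layout$placing_pad
  key_c <- rect_center(layout$start_key)

  # --- brick inventory -------------------------------------------------
  # six target-colored bricks (3 small, 3 large) placed by quadrant weights
  n_bricks <- 6L
  sizes <- c(rep("small", 3), rep("large", 3))
  qs <- sample.int(4L, n_bricks, replace = TRUE, prob = params$quadrant_weights)
  quads <- pad_quadrants(pick)
  margin <- 2
  bx <- by <- numeric(n_bricks)
  for (i in seq_len(n_bricks)) {
    q <- quads[[qs[i]]]
    for (tryi in 1:40) {
      cand <- c(stats::runif(1, q[["xmin"]] + margin, q[["xmax"]] - margin),
                stats::runif(1, q[["ymin"]] + margin, q[["ymax"]] - margin))
      if (i == 1L ||
          min(sqrt((bx[seq_len(i - 1)] - cand[1])^2 +
                   (by[seq_len(i - 1)] - cand[2])^2)) > 3) break
    }
    bx[i] <- cand[1]; by[i] <- cand[2]
  }
  bricks <- tibble::tibble(x = bx, y = by, size = sizes,
                           color = as.character(spec$target_color),
                           quadrant = qs)

  # --- target selection sequence --------------------------------------
  p_large <- stats::plogis(stats::qlogis(params$p_large_first[[instr]]) +
                             effects$logit_large)
  first_large <- stats::runif(1) < p_large
  pool <- seq_len(n_bricks)
  cand1 <- pool[bricks$size == (if (first_large) "large" else "small")]
  d_key <- sqrt((bricks$x - key_c[1])^2 + (bricks$y - key_c[2])^2)
  sel <- cand1[which.min(d_key[cand1])]
  order_sel <- sel
  pool <- setdiff(pool, sel)
  cur <- c(bricks$x[sel], bricks$y[sel])
  while (length(order_sel) < k) {
    d <- sqrt((bricks$x[pool] - cur[1])^2 + (bricks$y[pool] - cur[2])^2)
    sel <- pool[which.min(d)]
    order_sel <- c(order_sel, sel)
    pool <- setdiff(pool, sel)
    cur <- c(bricks$x[sel], bricks$y[sel])
  }

  # --- deposit locations (lower-right bias on the placing pad) ---------
  base <- c(place[["xmax"]] - 6, place[["ymin"]] + 8)
  spread <- switch(instr, pile = 0.6, collect = 2.5, sort = 0)
  placed <- matrix(0, k, 2)
  for (j in seq_len(k)) {
    if (instr == "sort") {
      gx <- base[1] - 6 * ((j - 1) %% 3)
      gy <- base[2] + 6 * ((j - 1) %/% 3)
      placed[j, ] <- c(gx, gy) + stats::rnorm(2, 0, 0.3)
    } else {
      placed[j, ] <- base + stats::rnorm(2, 0, spread)
    }
    placed[j, 1] <- min(max(placed[j, 1], place[["xmin"]] + 1.5),
                        place[["xmax"]] - 1.5)
    placed[j, 2] <- min(max(placed[j, 2], place[["ymin"]] + 1.5),
                        place[["ymax"]] - 1.5)
  }

  targets <- cbind(bricks$x[order_sel], bricks$y[order_sel])
  if (!all(rect_contains(pick, targets[, 1], targets[, 2]))) {
    stop("invalid layout: targets fall outside the picking pad", call. = FALSE)
  }

  # --- leg plan --------------------------------------------------------
  f_tr <- params$deceleration_fraction[[instr]] + effects$decel +
    effects$decel_instr[[instr]]
  f_re <- params$reach_deceleration_fraction + effects$decel
  clamp_f <- function(f) min(max(f, 0.2), 0.8)
  legs <- list()
  pt <- key_c
  for (j in seq_len(k)) {
    legs[[length(legs) + 1L]] <-
      list(from = pt, to = targets[j, ], phase = "reach", index = j,
           f = clamp_f(f_re + stats::rnorm(1, 0, params$sd_f_trial)))
    legs[[length(legs) + 1L]] <-
      list(from = targets[j, ], to = placed[j, ], phase = "transport",
           index = j,
           f = clamp_f(f_tr + stats::rnorm(1, 0, params$sd_f_trial)))
    pt <- placed[j, ]
  }
  legs[[length(legs) + 1L]] <-
    list(from = pt, to = key_c, phase = "return", index = NA_integer_,
         f = 0.5)

  artifact <- stats::runif(1) < params$p_artifact && k >= 2
  merge_at <- if (artifact) sample.int(k - 1, 1) else NA_integer_
  # merge transport `merge_at` with the following reach: the object is
  # dropped at speed, so there is no stop at the placing pad

  # --- assemble the frame-by-frame path --------------------------------
  onset_ms <- max(150, stats::rnorm(1, params$onset_mean_ms + effects$onset_ms,
                                    params$onset_sd_ms))
  dwell_frames <- max(1L, round(params$dwell_ms / ms_per_frame))
  leg_frames <- function(mult = 1) {
    max(20L, round(mult * stats::rnorm(1, params$leg_duration_ms,
                                       params$leg_duration_sd_ms) /
                     ms_per_frame))
  }
  sagitta <- function() stats::rnorm(1, params$curvature, params$curvature_sd) *
    sample(c(-1, 1), 1)

  xs <- ys <- numeric(0)
  gt <- list()
  idle0 <- round((spec$audio_end_time_ms + onset_ms) / ms_per_frame)
  xs <- rep(key_c[1], idle0); ys <- rep(key_c[2], idle0)

  j <- 1L
  while (j <= length(legs)) {
    lg <- legs[[j]]
    if (artifact && lg$phase == "transport" && !is.na(merge_at) &&
        lg$index == merge_at) {
      # merged transport + reach: one continuous profile over both chords
      nxt <- legs[[j + 1L]]
      nf <- leg_frames(2)
      c1 <- bezier_arclength_curve(lg$from, lg$to, sagitta())
      c2 <- bezier_arclength_curve(nxt$from, nxt$to, sagitta())
      tot <- c1$length + c2$length
      u <- seq(0, 1, length.out = nf + 1)[-1]
      frac <- leg_profile(u, 0.5) * tot
      xy <- rbind(c1$at(pmin(frac, c1$length) / c1$length)[frac <= c1$length, ,
                                                           drop = FALSE],
                  c2$at(pmax(frac - c1$length, 0) / c2$length)[frac > c1$length, ,
                                                               drop = FALSE])
      start_f <- length(xs) + 1L
      xs <- c(xs, xy[, 1]); ys <- c(ys, xy[, 2])
      gt[[length(gt) + 1L]] <- tibble::tibble(
        phase = "artifact", index = lg$index,
        start_frame = start_f, end_frame = length(xs),
        decel_fraction = NA_real_, distance_cm = tot)
      # grasp dwell at the reached target
      xs <- c(xs, rep(nxt$to[1], dwell_frames))
      ys <- c(ys, rep(nxt$to[2], dwell_frames))
      j <- j + 2L
      next
    }
    nf <- leg_frames()
    leg <- make_leg(lg$from, lg$to, nf, f = lg$f, sagitta = sagitta())
    start_f <- length(xs) + 1L # leg onset: last frame at rest is start_f - 1
    xs <- c(xs, leg$xy[, 1]); ys <- c(ys, leg$xy[, 2])
    if (lg$phase %in% c("reach", "transport")) {
      gt[[length(gt) + 1L]] <- tibble::tibble(
        phase = lg$phase, index = lg$index,
        start_frame = start_f - 1L, end_frame = length(xs),
        decel_fraction = lg$f, distance_cm = leg$length)
    }
    if (lg$phase != "return") {
      xs <- c(xs, rep(lg$to[1], dwell_frames))
      ys <- c(ys, rep(lg$to[2], dwell_frames))
    }
    j <- j + 1L
  }
  # trailing rest on the key
  xs <- c(xs, rep(key_c[1], 60))
  ys <- c(ys, rep(key_c[2], 60))

  n <- length(xs)
  # --- measurement model ----------------------------------------------
  px <- xs / layout$pixel_scale
  py <- ys / layout$pixel_scale
  lik <- pmin(0.999, 0.99 + stats::rnorm(n, 0, 0.003))
  if (params$noise_sd_px > 0) {
    px <- px + ar1_noise(n, params$noise_sd_px, params$noise_ar)
    py <- py + ar1_noise(n, params$noise_sd_px, params$noise_ar)
  }
  if (params$p_likelihood_dropout > 0) {
    drop <- stats::runif(n) < params$p_likelihood_dropout
    lik[drop] <- stats::runif(sum(drop), 0, 0.7)
    sd10 <- 10 * max(params$noise_sd_px, 0.5)
    px[drop] <- px[drop] + stats::rnorm(sum(drop), 0, sd10)
    py[drop] <- py[drop] + stats::rnorm(sum(drop), 0, sd10)
  }

  segments <- dplyr::bind_rows(gt)
  ground_truth <- list(
    segments = segments,
    onset_ms = onset_ms,
    first_target_size = bricks$size[order_sel[1]],
    target_quadrants = bricks$quadrant[order_sel],
    artifact = artifact,
    picked = bricks[order_sel, ],
    placed = tibble::tibble(x = placed[, 1], y = placed[, 2],
                            size = bricks$size[order_sel],
                            color = bricks$color[order_sel]),
    static = bricks[setdiff(seq_len(n_bricks), order_sel), ]
  )
  list(
    track = keypoint_track(px, py, lik, fps = fps,
                           pixel_scale = layout$pixel_scale),
    ground_truth = ground_truth
  )
}

# Stationary AR(1) noise with marginal SD `sd` and lag-1 correlation `rho`.
ar1_noise <- function(n, sd, rho) {
  if (rho <= 0) return(stats::rnorm(n, 0, sd))
  e <- stats::rnorm(n, 0, sd * sqrt(1 - rho^2))
  as.numeric(stats::filter(e, rho, method = "recursive",
                           init = stats::rnorm(1, 0, sd)))
}
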