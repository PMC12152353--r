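test_that("schedules are balanced within blocks and over nine blocks", {
  for (seed in c(1, 42)) {
    sched <- generate_schedule(seed = seed, n_blocks = 9)
    expect_equal(nrow(sched), 81)
    per_block <- table(sched$block, sched$instruction)
    expect_true(all(per_block == 3))
    per_block_col <- table(sched$block, sched$target_color)
    expect_true(all(per_block_col == 3))
    triples <- table(sched$instruction, sched$target_color,
                     sched$search_size)
    expect_true(all(triples == 3))
  }
  one <- generate_schedule(seed = 5, n_blocks = 1)
  expect_equal(nrow(one), 9)
  expect_true(all(table(one$instruction) == 3))
  expect_true(all(table(one$target_color) == 3))
})

test_that("schedule generation rejects invalid block counts", {
  expect_error(generate_schedule(1, n_blocks = 0), "positive integer")
  expect_error(generate_schedule(1, n_blocks = 2.5), "positive integer")
})

test_that("trial trajectories alternate reach/transport with planted counts", {
  for (k in c(3, 5)) {
    tr <- make_trial(seed = k, search_size = k)
    gt <- tr$ground_truth$segments
    expect_equal(sum(gt$phase == "reach"), k)
    expect_equal(sum(gt$phase == "transport"), k)
    expect_equal(gt$phase, rep(c("reach", "transport"), k))
    expect_true(all(gt$start_frame < gt$end_frame))
    expect_true(all(diff(gt$start_frame) > 0))
  }
})

test_that("noise-free speed is zero in dwells and positive inside legs", {
  tr <- make_trial(seed = 3)
  sp <- compute_speed(tr$track)
  gt <- tr$ground_truth$segments
  for (i in seq_len(nrow(gt))) {
    inside <- (gt$start_frame[i] + 5):(gt$end_frame[i] - 5)
    expect_true(all(sp[inside] > 0))
    if (i < nrow(gt)) {
      dwell <- (gt$end_frame[i] + 2):(gt$start_frame[i + 1] - 2)
      expect_true(all(sp[dwell] == 0))
    }
  }
})

test_that("planted deceleration fractions are recoverable from ground truth", {
  # raw (unsmoothed) speed within true boundaries must place the peak at
  # the planted fraction up to frame quantisation
  p <- clean_params(sd_f_trial = 0)
  tr <- make_trial(seed = 9, instruction = "pile", params = p)
  gt <- tr$ground_truth$segments
  sp <- compute_speed(tr$track)
  for (i in seq_len(nrow(gt))) {
    seg_speed <- sp[gt$start_frame[i]:gt$end_frame[i]]
    rec <- deceleration_time(seg_speed)
    nf <- gt$end_frame[i] - gt$start_frame[i]
    expect_lt(abs(rec - 100 * gt$decel_fraction[i]), 100 * 2 / nf)
  }
})

test_that("symmetric minimum-jerk legs have 50% deceleration and exact profile", {
  expect_equal(leg_profile(0.5, 0.5), 0.5)
  expect_equal(leg_profile(c(0, 1), 0.7), c(0, 1))
  # speed peak (max increment) sits at the planted fraction
  u <- seq(0, 1, length.out = 2001)
  for (f in c(0.4, 0.5, 0.547)) {
    v <- diff(leg_profile(u, f))
    expect_equal(which.max(v) / length(v), 1 - f, tolerance = 0.002)
  }
  # monotone non-decreasing distance profile
  expect_true(all(diff(leg_profile(u, 0.547)) >= -1e-12))
})

test_that("trajectory generation is reproducible under a fixed seed", {
  a <- make_trial(seed = 7)
  b <- make_trial(seed = 7)
  expect_identical(a$track$x, b$track$x)
  expect_identical(a$track$likelihood, b$track$likelihood)
  expect_identical(a$ground_truth$segments, b$ground_truth$segments)
})

test_that("cohorts have the planned size and recover planted selection bias", {
  p <- cohort_params(n_participants = 24, trials_per_participant = 81)
  coh <- generate_cohort(p, tracks = FALSE)
  expect_equal(nrow(coh$trials), 1944)
  expect_equal(length(unique(coh$trials$participant_id)), 24)

  p2 <- cohort_params(n_participants = 10, trials_per_participant = 27,
                      seed = 21)
  coh2 <- generate_cohort(p2)
  expect_equal(length(coh2$tracks), 270)
  pile <- coh2$trials[coh2$trials$instruction == "pile", ]
  p_hat <- mean(pile$first_target_size == "large")
  expect_lt(abs(p_hat - p2$p_large_first[["pile"]]), 0.10)
  # cohorts are reproducible
  coh2b <- generate_cohort(p2)
  expect_identical(coh2$tracks[[5]]$x, coh2b$tracks[[5]]$x)
})

test_that("cohort parameter validation catches invalid inputs", {
  expect_error(cohort_params(trials_per_participant = 10), "multiple of 9")
  expect_error(cohort_params(quadrant_weights = c(1, 1, 1, 1)), "summing to 1")
  expect_error(cohort_params(p_large_first = c(collect = 1.5, sort = 0.8,
                                               pile = 0.9)), "\\[0, 1\\]")
})

test_that("scene pairs differ only where bricks were picked or placed", {
  lay <- default_layout
  pick <- lay$picking_pad
  brick <- data.frame(x = pick[["xmin"]] + 5, y = pick[["ymin"]] + 6,
                      size = "large", color = "red")
  placed <- data.frame(x = lay$placing_pad[["xmin"]] + 5,
                       y = lay$placing_pad[["ymin"]] + 5,
                       size = "large", color = "red")
  # nothing picked: identical images
  pair0 <- generate_scene_pair(lay, placed_positions = NULL,
                               picked_positions = NULL, seed = 2,
                               static = brick)
  expect_identical(pair0$start, pair0$end)
  # seeded determinism, bit-identical
  pair1 <- generate_scene_pair(lay, placed, brick, seed = 3)
  pair2 <- generate_scene_pair(lay, placed, brick, seed = 3)
  expect_identical(pair1$start, pair2$start)
  expect_identical(pair1$end, pair2$end)
  # off-pad positions are rejected
  expect_error(
    generate_scene_pair(lay, placed_positions = brick,
                        picked_positions = NULL, seed = 1),
    "on their pad")
})
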