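test_that("position probability is 1 inside and Gaussian outside", {
  r <- region_rect(0, 10, 0, 10)
  expect_equal(position_probability(5, 5, r, sd = 3), 1)
  expect_equal(position_probability(13, 5, r, sd = 3), exp(-0.5))
  expect_lt(position_probability(40, 5, r, sd = 3), 1e-7)
  # union of regions: proximity to the nearest
  r2 <- region_rect(100, 110, 0, 10)
  expect_equal(position_probability(105, 5, list(r, r2), sd = 3), 1)
  expect_error(region_rect(5, 5, 0, 1), "degenerate")
})

test_that("objective is the elementwise product of its components", {
  ones <- rep(1, 20)
  obj <- build_objective(ones, ones, ones, ones, ones, kind = "start")
  expect_equal(obj$objective, ones)
  gate <- ones; gate[7] <- 0
  obj2 <- build_objective(ones, ones, ones, ones, gate, kind = "end")
  expect_equal(obj2$objective[7], 0)
  expect_equal(obj2$objective[-7], ones[-7])
  expect_error(build_objective(ones, ones[-1], ones, ones, ones),
               "same length")
})

test_that("event detection respects height, distance and tie-breaking", {
  idx <- 1:400
  bump <- function(c0) exp(-0.5 * ((idx - c0) / 6)^2)
  expect_equal(detect_events(bump(100)), 100)
  # two equal bumps 30 frames apart with min distance 50: earlier one wins
  expect_equal(detect_events(pmax(bump(100), bump(130)), min_distance = 50),
               100)
  # far enough apart: both kept, sorted
  expect_equal(detect_events(pmax(bump(100), bump(200))), c(100, 200))
  expect_equal(detect_events(rep(0, 100)), integer(0))
  expect_equal(detect_events(0.05 * bump(50), min_height = 0.1), integer(0))
})

test_that("mutual suppression windows sit at the expected offsets", {
  n <- 400
  flat <- rep(0.8, n)
  cfg <- segmentation_config()
  # no provisional events: identity
  un <- apply_mutual_suppression(flat, flat, config = cfg)
  expect_identical(un$start, flat)
  expect_identical(un$end, flat)
  # a single start at f: end objective peaks near f + 100, floor near f
  f <- 120
  sup <- apply_mutual_suppression(flat, flat, starts = f, config = cfg)
  expect_equal(which.max(sup$end), f + cfg$suppression_offset)
  expect_equal(sup$end[f], 0.8 * cfg$suppression_floor, tolerance = 1e-3)
  # symmetric for ends
  sup2 <- apply_mutual_suppression(flat, flat, ends = 300, config = cfg)
  expect_equal(which.max(sup2$start), 300 - cfg$suppression_offset)
})

test_that("clean trials segment into the planted movements within 5 frames", {
  for (seed in c(2, 4)) {
    tr <- make_trial(seed = seed)
    res <- segment_trial(tr$track, tr$spec)
    expect_true(res$reach_ok)
    expect_true(res$transport_ok)
    k <- tr$spec$search_size
    expect_equal(sum(res$segments$phase == "reach"), k)
    expect_equal(sum(res$segments$phase == "transport"), k)
    m <- merge(as.data.frame(res$segments),
               as.data.frame(tr$ground_truth$segments),
               by = c("phase", "index"))
    expect_true(all(abs(m$start_frame.x - m$start_frame.y) <= 5))
    expect_true(all(abs(m$end_frame.x - m$end_frame.y) <= 5))
    # detected segments never overlap and phases alternate
    segs <- res$segments[order(res$segments$start_frame), ]
    expect_true(all(diff(segs$start_frame) > 0))
    expect_true(all(segs$phase == rep(c("reach", "transport"), k)))
    expect_true(all(segs$end_frame[-nrow(segs)] <= segs$start_frame[-1]))
  }
})

test_that("segmentation is deterministic for identical input", {
  tr <- make_trial(seed = 6, params = cohort_params())
  a <- segment_trial(tr$track, tr$spec)
  b <- segment_trial(tr$track, tr$spec)
  expect_identical(a$segments, b$segments)
})

test_that("dropped-object artifacts produce count-mismatch discards", {
  p <- clean_params(p_artifact = 1)
  tr <- make_trial(seed = 11, search_size = 4, params = p)
  expect_true(tr$ground_truth$artifact)
  res <- segment_trial(tr$track, tr$spec)
  expect_false(res$reach_ok)
  expect_false(res$transport_ok)
  expect_equal(res$reach_reason, "count-mismatch")
  expect_equal(nrow(res$segments), 0)
})

test_that("raising the speed threshold never increases detected events", {
  tr <- make_trial(seed = 8, params = cohort_params())
  trk <- interpolate_low_confidence(tr$track)
  kin <- kinematic_series(trk)
  lay <- default_layout
  counts <- vapply(c(15, 30, 60, 120), function(thr) {
    cfg <- segmentation_config(speed_threshold = thr)
    so <- trial_objective(trk, kin, list(lay$start_key, lay$placing_pad),
                          "start", cfg)$objective
    length(detect_events(so, cfg$peak_min_distance, cfg$peak_min_height))
  }, integer(1))
  expect_true(all(diff(counts) <= 0))
})

test_that("participant exclusion uses the strict one-third rule", {
  expect_equal(qc_participant(rep(c(TRUE, FALSE), c(27, 54))), "keep")
  expect_equal(qc_participant(rep(c(TRUE, FALSE), c(28, 53))), "exclude")
  expect_equal(qc_participant(rep(FALSE, 81)), "keep")
  expect_error(qc_participant(logical(0)), "no trial statuses")
})
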