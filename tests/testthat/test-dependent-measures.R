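test_that("deceleration time is the fraction of duration after peak speed", {
  expect_equal(deceleration_time(c(0, 1, 2, 3, 2, 1, 0)), 50)
  expect_equal(deceleration_time(1:5), 0)
  expect_equal(deceleration_time(5:1), 100)
  # ties resolve to the first attaining frame
  expect_equal(deceleration_time(c(0, 3, 3, 0, 0)), 75)
  expect_error(deceleration_time(1), "at least 2")
})

test_that("reversing a unique-peak speed profile mirrors deceleration time", {
  set.seed(3)
  for (i in 1:20) {
    s <- cumsum(rnorm(30))
    if (sum(s == max(s)) != 1) next
    expect_equal(deceleration_time(rev(s)), 100 - deceleration_time(s))
  }
})

test_that("path ratio measures excursion from the straight line", {
  expect_equal(path_ratio(seq(0, 10, length.out = 50),
                          seq(0, 5, length.out = 50)), 1)
  th <- seq(0, pi, length.out = 2000)
  expect_equal(path_ratio(cos(th), sin(th)), pi / 2, tolerance = 1e-5)
  expect_error(path_ratio(c(1, 2, 1), c(1, 3, 1)), "coincident")
})

test_that("path ratio is invariant under rotation, translation and scaling", {
  set.seed(5)
  x <- cumsum(runif(40, 0.5, 1)); y <- cumsum(rnorm(40, 0, 0.3))
  r0 <- path_ratio(x, y)
  a <- 0.7
  expect_equal(path_ratio(cos(a) * x - sin(a) * y, sin(a) * x + cos(a) * y),
               r0)
  expect_equal(path_ratio(x + 40, y - 11), r0)
  expect_equal(path_ratio(2.5 * x, 2.5 * y), r0)
  expect_gte(r0, 1)
})

test_that("movement onset is measured from the audio offset", {
  expect_equal(as.numeric(movement_onset(113, 0)), 560) # frame 113 at 200 fps
  expect_equal(as.numeric(movement_onset(101, 500)), 0)
  early <- movement_onset(41, 500)
  expect_equal(as.numeric(early), -300)
  expect_true(attr(early, "early_start"))
  expect_error(movement_onset(100, NA), "missing audio")
})

test_that("segment summaries compute the tabulated dependent variables", {
  # straight 100 px move at constant speed
  n <- 101
  trk <- keypoint_track(seq(0, 100, length.out = n), rep(0, n))
  seg <- list(start_frame = 1, end_frame = n)
  out <- summarize_segment(trk, seg)
  expect_equal(out$distance_cm, 100 * 0.042)
  expect_equal(out$duration_ms, (n - 1) * 5)
  expect_equal(out$avg_speed_cm_s, out$peak_speed_cm_s, tolerance = 1e-9)
  expect_equal(out$path_ratio, 1)
  expect_gte(out$peak_speed_cm_s, out$avg_speed_cm_s)
  expect_error(summarize_segment(trk, list(start_frame = 50, end_frame = 50)),
               "invalid segment")
})

test_that("planted leg lengths are recovered to within one percent", {
  tr <- make_trial(seed = 13)
  gt <- tr$ground_truth$segments
  kin <- kinematic_series(tr$track)
  for (i in seq_len(nrow(gt))) {
    out <- summarize_segment(tr$track,
                             list(start_frame = gt$start_frame[i],
                                  end_frame = gt$end_frame[i]), kin)
    expect_equal(out$distance_cm, gt$distance_cm[i],
                 tolerance = 0.01)
  }
  # average speed x duration tracks distance on clean segments
  i <- 2
  out <- summarize_segment(tr$track,
                           list(start_frame = gt$start_frame[i],
                                end_frame = gt$end_frame[i]), kin)
  expect_equal(out$avg_speed_cm_s * out$duration_ms / 1000,
               out$distance_cm, tolerance = 0.08)
})
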