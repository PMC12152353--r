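test_that("keypoint tracks round-trip through CSV bit-exactly", {
  trk <- keypoint_track(x = c(1.5, 2.25, 3.125), y = c(4, 5, 6),
                        likelihood = c(0.99, 0.5, 0.87))
  path <- withr::local_tempfile(fileext = ".csv")
  write_keypoint_track(trk, path)
  back <- load_keypoint_track(path, "index_mcp")
  expect_identical(back$x, trk$x)
  expect_identical(back$y, trk$y)
  expect_identical(back$likelihood, trk$likelihood)
  expect_error(load_keypoint_track(path, "thumb_tip"), "not found")
  expect_error(load_keypoint_track(file.path(tempdir(), "nope.csv")),
               "file not found")
})

test_that("track construction validates its invariants", {
  expect_error(keypoint_track(1:3, 1:2), "equal length")
  expect_error(keypoint_track(1:3, 1:3, c(0.5, 0.5, 1.2)), "\\[0, 1\\]")
  expect_error(keypoint_track(1:3, 1:3, fps = 0), "positive")
})

test_that("low-confidence samples are linearly interpolated", {
  # single dropout: midpoint fill
  trk <- keypoint_track(c(0, 99, 10), c(0, -50, 0),
                        likelihood = c(0.95, 0.2, 0.95))
  out <- interpolate_low_confidence(trk)
  expect_equal(out$x, c(0, 5, 10))
  expect_equal(out$y, c(0, 0, 0))
  # dropout run of 3 between x = 2 and x = 10: evenly spaced fill
  trk3 <- keypoint_track(c(2, 0, 0, 0, 10), rep(0, 5),
                         likelihood = c(0.9, 0.1, 0.2, 0.3, 0.9))
  expect_equal(interpolate_low_confidence(trk3)$x, c(2, 4, 6, 8, 10))
  # fully confident track is returned unchanged
  ok <- keypoint_track(1:5, 5:1, likelihood = rep(0.95, 5))
  expect_identical(interpolate_low_confidence(ok), ok)
})

test_that("interpolation is idempotent and extends edges by nearest value", {
  trk <- keypoint_track(c(7, 7, 3, 9, 9), c(1, 1, 2, 5, 5),
                        likelihood = c(0.1, 0.3, 0.95, 0.9, 0.5))
  once <- interpolate_low_confidence(trk)
  expect_equal(once$x[1:2], c(3, 3)) # leading run: nearest confident value
  expect_equal(once$x[5], 9)         # trailing run
  twice <- interpolate_low_confidence(once)
  expect_equal(twice$x, once$x)
  expect_equal(twice$y, once$y)
  # confident frames are never altered
  expect_identical(once$x[3:4], c(3, 9))
})

test_that("tracks with no confident frame are unrecoverable", {
  bad <- keypoint_track(1:4, 1:4, likelihood = rep(0.4, 4))
  expect_error(interpolate_low_confidence(bad), "unrecoverable")
})

test_that("physical calibration maps pixels to cm and frames to ms", {
  trk <- keypoint_track(x = rep(100, 50), y = rep(0, 50),
                        fps = 200, pixel_scale = 0.042)
  phys <- to_physical(trk)
  expect_equal(phys$time_ms[1], 0)
  expect_equal(phys$x_cm[1], 4.2)
  expect_equal(frames_to_ms(50, 200), 250)
  expect_equal(diff(phys$time_ms)[1], 5)
  # conversion is linear and invertible
  expect_equal(phys$x_cm / trk$pixel_scale, trk$x)
})
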