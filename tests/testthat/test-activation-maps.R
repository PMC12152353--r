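lay <- default_layout

brick_at <- function(pad, dx, dy, size = "large", color = "red") {
  data.frame(x = pad[["xmin"]] + dx, y = pad[["ymin"]] + dy,
             size = size, color = color)
}

test_that("binarization keeps saturated bright pixels only", {
  gray <- array(140 / 255, dim = c(40, 60, 3))
  expect_true(all(binarize_scene(gray) == 0))
  img <- gray
  img[10:20, 30:40, 1] <- 0.9; img[10:20, 30:40, 2:3] <- 0.1
  mask <- binarize_scene(img)
  expect_true(all(mask[10:20, 30:40] == 255))
  expect_true(all(mask[-(10:20), ] == 0))
  expect_equal(sum(mask > 0), 11 * 11)
  expect_error(binarize_scene(matrix(1, 5, 5)), "RGB")
})

test_that("identical scenes yield an all-zero activation map", {
  pair <- generate_scene_pair(lay, seed = 2,
                              static = brick_at(lay$picking_pad, 5, 6))
  am <- activation_map(pair$start, pair$end, "picking", lay)
  expect_true(all(am$values == 0))
  expect_equal(unname(am$quadrant_means), rep(0, 4))
})

test_that("a single picked brick activates only its quadrant", {
  # near-left quadrant of the picking pad (quadrant 3)
  picked <- brick_at(lay$picking_pad, 5, 6)
  placed <- brick_at(lay$placing_pad, 5, 5)
  pair <- generate_scene_pair(lay, placed, picked, seed = 3)
  am <- activation_map(pair$start, pair$end, "picking", lay)
  qm <- am$quadrant_means
  expect_gt(qm[["q3"]], 0)
  expect_true(all(qm[c("q1", "q2", "q4")] < 0.02 * qm[["q3"]]))
  # absolute difference: argument order does not matter
  am_rev <- activation_map(pair$end, pair$start, "picking", lay)
  expect_equal(am$values, am_rev$values)
})

test_that("equal-size changes in different quadrants activate them equally", {
  picked <- rbind(brick_at(lay$picking_pad, 5, 6),   # near-left
                  brick_at(lay$picking_pad, 16, 24)) # far-right
  placed <- rbind(brick_at(lay$placing_pad, 5, 5),
                  brick_at(lay$placing_pad, 5, 10))
  # fix identical footprints so the two changes are exactly congruent
  picked$w_cm <- 1.6; picked$h_cm <- 2.4
  placed$w_cm <- 1.6; placed$h_cm <- 2.4
  start <- render_scene(picked, lay)
  end <- render_scene(NULL, lay)
  am <- activation_map(start, end, "picking", lay)
  qm <- am$quadrant_means
  expect_equal(qm[["q3"]], qm[["q2"]], tolerance = 0.02)
  expect_lt(qm[["q1"]], 0.02 * qm[["q3"]])
})

test_that("adding a removed brick never decreases total activation", {
  one <- brick_at(lay$picking_pad, 5, 6)
  two <- rbind(one, brick_at(lay$picking_pad, 15, 22))
  end <- render_scene(NULL, lay)
  am1 <- activation_map(render_scene(one, lay), end, "picking", lay)
  am2 <- activation_map(render_scene(two, lay), end, "picking", lay)
  expect_gte(sum(am2$values), sum(am1$values))
})

test_that("quadrant means partition the map and recover its global mean", {
  m <- matrix(7, 41, 61) # odd dimensions: remainder goes to near/right
  expect_equal(unname(quadrant_means(m)), rep(7, 4))
  set.seed(2)
  m2 <- matrix(runif(40 * 60), 40, 60)
  qm <- quadrant_means(m2)
  expect_equal(mean(qm), mean(m2), tolerance = 1e-12)
  # activation confined to the near-left block
  m3 <- matrix(0, 40, 60); m3[1:20, 1:30] <- 5
  qm3 <- quadrant_means(m3)
  expect_equal(qm3[["q3"]], 5)
  expect_equal(sum(qm3[c("q1", "q2", "q4")]), 0)
})

test_that("mismatched image sizes are rejected", {
  a <- array(0.5, dim = c(10, 10, 3))
  b <- array(0.5, dim = c(12, 10, 3))
  expect_error(activation_map(a, b, "picking", lay), "identical size")
})
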