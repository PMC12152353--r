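test_that("measures aggregate to participant x condition means", {
  df <- tibble::tibble(
    participant_id = c("P1", "P1", "P1", "P2"),
    instruction = c("pile", "pile", "sort", "pile"),
    search_size = c(3, 3, 3, 4),
    deceleration_pct = c(40, 60, 52, 55)
  )
  agg <- aggregate_measures(df, dvs = "deceleration_pct")
  expect_equal(nrow(agg), 3)
  pile_p1 <- agg$deceleration_pct[agg$participant_id == "P1" &
                                    agg$instruction == "pile"]
  expect_equal(pile_p1, 50)  # mean of 40 and 60
  expect_equal(agg$deceleration_pct[agg$participant_id == "P2"], 55)
  expect_equal(nrow(aggregate_measures(df[0, ], dvs = "deceleration_pct")), 0)
  expect_error(aggregate_measures(df, dvs = "nope"), "missing columns")
})

test_that("mean_ci matches the closed-form t interval", {
  expect_equal(unname(mean_ci(rep(3, 5))), c(3, 3, 3))
  # hand calculation for {1,2,3,4}: mean 2.5, sd = sqrt(5/3) = 1.2909944,
  # half-width = qt(.975, 3) * sd / sqrt(4) = 3.1824463 * 0.6454972
  ci <- mean_ci(c(1, 2, 3, 4))
  expect_equal(unname(ci), c(2.5, 0.4457399, 4.5542601), tolerance = 1e-6)
  expect_error(mean_ci(1), "at least 2")
})

test_that("t-based confidence intervals cover the mean at nominal rate", {
  set.seed(99)
  hits <- replicate(400, {
    ci <- mean_ci(rnorm(15, mean = 2))
    ci[["lower"]] <= 2 && 2 <= ci[["upper"]]
  })
  expect_gt(mean(hits), 0.90)
  expect_lt(mean(hits), 0.99)
})

test_that("the arcsine-square-root transform stabilises proportions", {
  expect_equal(round(arcsine_transform(0.5), 3), 0.785)
  expect_equal(arcsine_transform(0), 0)
  expect_equal(arcsine_transform(1), pi / 2)
  p <- seq(0, 1, 0.01)
  expect_true(all(diff(arcsine_transform(p)) > 0)) # strictly increasing
  expect_error(arcsine_transform(1.2), "\\[0, 1\\]")
  expect_error(arcsine_transform(-0.1), "\\[0, 1\\]")
})

test_that("JZS Bayes factors match independent quadrature oracles", {
  # two-sided: Cauchy-mixture (g) representation, fine trapezoid grid
  for (t in c(0, 0.8, 2.24, 3.3, 5)) {
    for (n in c(10, 24, 80)) {
      mine <- jzs_bf10(t, n, "two_sided")
      expect_equal(mine, oracle_bf10_two_sided(t, n), tolerance = 5e-5)
    }
  }
  # one-sided: truncated-prior grid quadrature
  for (t in c(-1, 0.5, 2.5)) {
    expect_equal(jzs_bf10(t, 24, "greater"),
                 oracle_bf10_one_sided(t, 24, direction = "greater"),
                 tolerance = 5e-4)
  }
})

test_that("Bayes factors behave lawfully across effect sizes", {
  # t = 0 favours the null at any n
  for (n in c(5, 24, 100)) {
    expect_lt(jzs_bf10(0, n), 1)
  }
  # BF10 * BF01 = 1 by construction
  res <- jzs_ttest_bf(c(1.1, 0.3, 0.8, 1.4, 0.2, 0.9), mu = 0,
                      design = "one_sample")
  expect_equal(res$bf10 * res$bf01, 1)
  # monotone in |t| for fixed n, two-sided
  bfs <- vapply(c(0, 0.5, 1, 2, 3, 4), jzs_bf10, numeric(1), n = 24)
  expect_true(all(diff(bfs) > 0))
  # direction symmetry: BF+0(x, y) = BF-0(y, x)
  set.seed(11)
  x <- rnorm(20, 0.5); y <- rnorm(20)
  expect_equal(jzs_ttest_bf(x, y, design = "paired",
                            direction = "greater")$bf10,
               jzs_ttest_bf(y, x, design = "paired",
                            direction = "less")$bf10)
  expect_error(jzs_ttest_bf(rep(2, 8), rep(1, 8), design = "paired"),
               "zero variance")
})

test_that("planted extreme proportions give decisive one-sample evidence", {
  set.seed(23)
  props <- plogis(rnorm(24, qlogis(0.85), 0.3))
  res <- jzs_ttest_bf(arcsine_transform(props),
                      mu = arcsine_transform(0.5),
                      design = "one_sample", direction = "greater")
  expect_gt(res$bf10, 100)
})
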