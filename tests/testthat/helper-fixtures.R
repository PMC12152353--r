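# Shared fixtures: everything is generated in code at test time.

default_layout <- workspace_layout()

# Small, clean (noise-free, dropout-free) cohort parameters for structural
# tests where measurement noise would only obscure the property under test.
clean_params <- function(...) {
  cohort_params(noise_sd_px = 0, p_likelihood_dropout = 0, ...)
}

# One simulated trial plus its ground truth, seeded.
make_trial <- function(seed = 1, instruction = NULL, search_size = NULL,
                       params = clean_params(), layout = default_layout) {
  sched <- generate_schedule(seed = seed, n_blocks = 3)
  keep <- rep(TRUE, nrow(sched))
  if (!is.null(instruction)) keep <- keep & sched$instruction == instruction
  if (!is.null(search_size)) keep <- keep & sched$search_size == search_size
  i <- which(keep)[1]
  stopifnot(!is.na(i))
  spec <- sched[i, ]
  spec$trial_id <- sprintf("fixture_%d", seed)
  set.seed(seed * 1000 + 17)
  sim <- generate_trial_trajectory(spec, layout, params)
  c(sim, list(spec = spec))
}

# Independent Bayes-factor oracle for the two-sided JZS test: the
# g-representation of the Cauchy prior (normal mixed over an
# inverse-gamma(1/2, 1/2) scale), evaluated by fixed fine-grid trapezoid
# quadrature. Shares no code path with jzs_bf10().
oracle_bf10_two_sided <- function(t, n, r = 1 / sqrt(2)) {
  nu <- n - 1
  f <- function(g) {
    (1 + n * g * r^2)^(-0.5) *
      (1 + t^2 / ((1 + n * g * r^2) * nu))^(-(nu + 1) / 2) *
      (2 * pi)^(-0.5) * g^(-1.5) * exp(-1 / (2 * g))
  }
  u <- seq(1e-7, 1 - 1e-7, length.out = 200001)
  g <- u / (1 - u)
  vals <- f(g) / (1 - u)^2
  num <- sum((vals[-1] + vals[-length(vals)]) / 2 * diff(u))
  num / (1 + t^2 / nu)^(-(nu + 1) / 2)
}

# One-sided oracle: trapezoid quadrature of the noncentral-t likelihood
# against the half-line-truncated Cauchy prior on a fixed fine grid.
oracle_bf10_one_sided <- function(t, n, r = 1 / sqrt(2),
                                  direction = "greater") {
  nu <- n - 1
  delta <- seq(0, 15 * r, length.out = 60001)
  if (direction == "less") delta <- -delta
  like <- suppressWarnings(stats::dt(t, df = nu, ncp = delta * sqrt(n)))
  prior <- 2 * stats::dcauchy(delta, 0, r)
  vals <- like * prior
  w <- abs(diff(delta))
  num <- sum((vals[-1] + vals[-length(vals)]) / 2 * w)
  num / stats::dt(t, df = nu)
}

# Boundary recovery errors (detected - true frames) over a cohort.
boundary_errors <- function(cohort, segmentation) {
  st <- segmentation$status
  ids <- st$trial_id[st$reach_ok & st$transport_ok]
  errs <- numeric(0)
  for (id in ids) {
    gt <- as.data.frame(cohort$ground_truth[[id]]$segments)
    dd <- as.data.frame(
      segmentation$segments[segmentation$segments$trial_id == id, ])
    m <- merge(dd, gt, by = c("phase", "index"))
    errs <- c(errs, m$start_frame.x - m$start_frame.y,
              m$end_frame.x - m$end_frame.y)
  }
  errs
}
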