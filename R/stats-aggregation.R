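#' Aggregate trial-level measures to participant x condition means
#'
#' Movement measures are first averaged within participant, placing
#' instruction and search size before any statistics, so each participant
#' contributes one value per condition cell.
#'
#' @param measures A data frame of trial- or segment-level measures.
#' @param dvs Character vector of dependent-variable columns to average.
#' @param keys Grouping columns (default participant, instruction, search
#'   size).
#' @return A tibble with one row per key combination, the mean of each
#'   dependent variable, and the number of contributing rows `n_obs`.
#' @export
aggregate_measures <- function(measures,
                               dvs,
                               keys = c("participant_id", "instruction",
                                        "search_size")) {
  if (nrow(measures) == 0L) return(tibble::tibble())
  missing_cols <- setdiff(c(keys, dvs), names(measures))
  if (length(missing_cols)) {
    stop("missing columns: ", paste(missing_cols, collapse = ", "),
         call. = FALSE)
  }
  measures |>
    dplyr::group_by(dplyr::across(dplyr::all_of(keys))) |>
    dplyr::summarise(
      dplyr::across(dplyr::all_of(dvs), ~ mean(.x, na.rm = TRUE)),
      n_obs = dplyr::n(), .groups = "drop"
    )
}

#' Mean with t-based confidence interval
#'
#' @param values Numeric sample (n >= 2).
#' @param level Confidence level (default 0.95).
#' @return Named numeric vector `mean`, `lower`, `upper`.
#' @examples
#' mean_ci(c(1, 2, 3, 4))
#' @export
mean_ci <- function(values, level = 0.95) {
  values <- values[!is.na(values)]
  n <- length(values)
  if (n < 2L) stop("need at least 2 values for a confidence interval",
                   call. = FALSE)
  m <- mean(values)
  half <- stats::qt(1 - (1 - level) / 2, df = n - 1) * stats::sd(values) / sqrt(n)
  c(mean = m, lower = m - half, upper = m + half)
}

#' Arcsine-square-root transform for proportions
#'
#' Variance-stabilising transform `asin(sqrt(p))` applied to proportions
#' before t-tests when they are extreme (outside 0.3-0.7). The chance
#' level p = 0.5 maps to `asin(sqrt(0.5)) = pi/4`, approximately 0.785,
#' which serves as the reference value for one-sample tests against
#' chance.
#'
#' @param p Proportion(s) in \[0, 1\].
#' @return Transformed value(s) in \[0, pi/2\].
#' @examples
#' arcsine_transform(0.5)  # 0.785
#' @export
arcsine_transform <- function(p) {
  if (any(is.na(p)) || any(p < 0 | p > 1)) {
    stop("proportions must lie in [0, 1]", call. = FALSE)
  }
  asin(sqrt(p))
}

#' Default-prior (JZS) Bayes-factor t-test
#'
#' Computes the Bayes factor BF10 of a paired or one-sample t-test under
#' the default Jeffreys-Zellner-Siow prior: standardized effect size
#' `delta ~ Cauchy(0, prior_scale)` under H1 (`prior_scale = 1/sqrt(2)`
#' by default) against the point null `delta = 0`. The marginal
#' likelihood under H1 is obtained by adaptive quadrature of the
#' noncentral-t likelihood against the Cauchy prior (relative tolerance
#' 1e-8); one-sided variants restrict the prior to the corresponding
#' half-line.
#'
#' @param x Numeric sample (first measure, or the sample itself for
#'   one-sample tests).
#' @param y Second measure for paired tests (same length as `x`), ignored
#'   for one-sample tests.
#' @param mu Null value for one-sample tests (default 0).
#' @param design `"paired"` or `"one_sample"`.
#' @param direction `"two_sided"`, `"greater"` (effect > 0, i.e. x > y or
#'   x > mu under H1) or `"less"`.
#' @param prior_scale Cauchy prior scale r (default `1/sqrt(2)`).
#' @return A list of class `bf_result`: `bf10`, `bf01`, `t_statistic`,
#'   `n`, `df`, `direction`, `prior_scale`.
#' @examples
#' jzs_ttest_bf(c(1.2, 0.8, 1.1, 1.4, 0.9), mu = 0,
#'              design = "one_sample", direction = "greater")
#' @export
jzs_ttest_bf <- function(x, y = NULL, mu = 0,
                         design = c("paired", "one_sample"),
                         direction = c("two_sided", "greater", "less"),
                         prior_scale = 1 / sqrt(2)) {
  design <- match.arg(design)
  direction <- match.arg(direction)
  d <- switch(design,
    paired = {
      if (is.null(y) || length(y) != length(x)) {
        stop("paired design needs `y` of the same length as `x`",
             call. = FALSE)
      }
      x - y
    },
    one_sample = x - mu
  )
  d <- d[!is.na(d)]
  n <- length(d)
  if (n < 2L) stop("need at least 2 observations", call. = FALSE)
  sdd <- stats::sd(d)
  if (sdd < .Machine$double.eps) {
    stop("degenerate data: zero variance of the differences", call. = FALSE)
  }
  t_stat <- mean(d) / (sdd / sqrt(n))
  bf10 <- jzs_bf10(t_stat, n, direction, prior_scale)
  structure(list(bf10 = bf10, bf01 = 1 / bf10, t_statistic = t_stat,
                 n = n, df = n - 1L, direction = direction,
                 prior_scale = prior_scale),
            class = "bf_result")
}

#' @export
print.bf_result <- function(x, ...) {
  cat(sprintf(
    "JZS t-test (Cauchy prior, r = %.4f, %s): t(%d) = %.3f, BF10 = %.4g\n",
    x$prior_scale, x$direction, x$df, x$t_statistic, x$bf10
  ))
  invisible(x)
}

#' Bayes factor from a t statistic
#'
#' Lower-level interface to the JZS Bayes factor for a given t statistic
#' and sample size (see [jzs_ttest_bf()]).
#'
#' @param t_stat Observed t statistic.
#' @param n Sample size (pairs for paired designs).
#' @param direction `"two_sided"`, `"greater"` or `"less"`.
#' @param prior_scale Cauchy prior scale.
#' @param rel_tol Relative tolerance of the quadrature.
#' @return BF10 as a single positive number.
#' @export
jzs_bf10 <- function(t_stat, n, direction = "two_sided",
                     prior_scale = 1 / sqrt(2), rel_tol = 1e-8) {
  df <- n - 1
  like <- function(delta) {
    stats::dt(t_stat, df = df, ncp = delta * sqrt(n)) *
      stats::dcauchy(delta, 0, prior_scale)
  }
  m0 <- stats::dt(t_stat, df = df)
  intg <- function(lo, hi) {
    # dt(ncp) warns about its ~1e-12 precision limit, far below rel_tol
    suppressWarnings(
      stats::integrate(like, lo, hi, rel.tol = rel_tol,
                       stop.on.error = FALSE)$value
    )
  }
  m1 <- switch(direction,
    two_sided = intg(-Inf, 0) + intg(0, Inf),
    greater = 2 * intg(0, Inf),
    less = 2 * intg(-Inf, 0),
    stop("unknown direction: ", direction, call. = FALSE)
  )
  m1 / m0
}
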