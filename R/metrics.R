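#' Mean total FTND score with its model-based standard error
#'
#' Mean over the non-missing totals; the model SE is the sample SD
#' (`n - 1` denominator) divided by the square root of the number of
#' scored subjects.
#'
#' @param totals Per-subject totals, possibly containing `NA`.
#' @return A list of class `ftnd_estimate` with `estimand = "mean_ftnd"`,
#'   `value`, `model_se`, `n_used` and `ok`.  Fewer than 2 usable totals is
#'   not an error: the estimate is returned with `ok = FALSE` and `NA`
#'   values so the replication can be recorded as undefined.
#' @export
mean_and_se <- function(totals) {
  x <- totals[!is.na(totals)]
  n <- length(x)
  if (n < 2L) {
    return(structure(list(estimand = "mean_ftnd", value = NA_real_,
                          model_se = NA_real_, n_used = n, ok = FALSE),
                     class = "ftnd_estimate"))
  }
  structure(list(estimand = "mean_ftnd", value = mean(x),
                 model_se = sd(x) / sqrt(n), n_used = n, ok = TRUE),
            class = "ftnd_estimate")
}

#' Simple linear regression slope of totals on a covariate
#'
#' Ordinary least squares with intercept, restricted to subjects with
#' non-missing totals; the model SE is the classical OLS slope standard
#' error.  Used for the association estimand: total FTND score regressed
#' on "Is smoking allowed in your home?".
#'
#' @param totals Per-subject totals, possibly containing `NA`.
#' @param x Explanatory covariate (same length, non-missing).
#' @return A list of class `ftnd_estimate` with
#'   `estimand = "regression_coefficient"`; `ok = FALSE` (with `NA` values)
#'   when fewer than 3 usable subjects remain or `x` is constant among
#'   them.
#' @export
ols_simple <- function(totals, x) {
  keep <- !is.na(totals) & !is.na(x)
  y <- totals[keep]; xv <- as.numeric(x[keep])
  n <- length(y)
  undefined <- structure(list(estimand = "regression_coefficient",
                              value = NA_real_, model_se = NA_real_,
                              n_used = n, ok = FALSE),
                         class = "ftnd_estimate")
  if (n < 3L) return(undefined)
  sxx <- sum((xv - mean(xv))^2)
  if (sxx <= 0) return(undefined)
  slope <- sum((xv - mean(xv)) * (y - mean(y))) / sxx
  intercept <- mean(y) - slope * mean(xv)
  rss <- sum((y - intercept - slope * xv)^2)
  se <- sqrt(rss / (n - 2L) / sxx)
  structure(list(estimand = "regression_coefficient", value = slope,
                 model_se = se, n_used = n, ok = TRUE),
            class = "ftnd_estimate")
}

#' Bias and percent bias of an estimate against its per-dataset truth
#'
#' Bias is `theta_hat - theta`; percent bias is `100 * (theta_hat - theta)
#' / theta`, where `theta` is the value computed on the same simulated
#' dataset before missingness was generated.
#'
#' @param estimate An `ftnd_estimate` (or a bare number).
#' @param truth The true value `theta` (or a list with a `value` element).
#' @param eps Guard on `|theta|` below which percent bias is undefined
#'   (`NA`); the absolute bias is still returned.
#' @return A list with `bias` and `percent_bias`.
#' @export
bias_and_percent <- function(estimate, truth, eps = 1e-8) {
  theta_hat <- if (is.list(estimate)) estimate$value else estimate
  theta <- if (is.list(truth)) truth$value else truth
  if (!is.finite(theta)) stop("`truth` must be finite", call. = FALSE)
  bias <- theta_hat - theta
  pct <- if (abs(theta) > eps) 100 * bias / theta else NA_real_
  list(bias = bias, percent_bias = pct)
}

#' Monte Carlo 95 percent interval of per-replication values
#'
#' Summarises the spread of a performance value across simulation
#' replications.  The default percentile interval is the 2.5th and 97.5th
#' percentiles of the replication values (linear interpolation between
#' order statistics); the normal-theory alternative is
#' `mean +/- 1.96 * SD`.
#'
#' @param values Per-replication values; `NA`s are dropped.
#' @param type `"percentile"` (default) or `"normal"`.
#' @return Numeric vector `c(low, high)` with `low <= high`.
#' @export
monte_carlo_ci <- function(values, type = c("percentile", "normal")) {
  type <- match.arg(type)
  x <- values[!is.na(values)]
  if (length(x) < 2L) stop("need at least 2 finite values", call. = FALSE)
  if (type == "percentile") {
    unname(quantile(x, c(0.025, 0.975), type = 7))
  } else {
    mean(x) + c(-1, 1) * qnorm(0.975) * sd(x)
  }
}

#' Standard-error bias summary for one simulation cell
#'
#' The empirical ("true") SE is the SD of the estimates across
#' replications.  Each replication's SE bias is its model SE minus the
#' empirical SE; percent SE bias divides by the empirical SE.  The summary
#' reports the empirical SE, the mean percent SE bias over replications,
#' and its Monte Carlo 95\% interval.
#'
#' @param model_ses Per-replication model-based SEs.
#' @param estimates Per-replication point estimates (same length).
#' @param ci_type Passed to [monte_carlo_ci()].
#' @return A list with `empirical_se`, `mean_percent_se_bias`, `ci` and
#'   `n_used` (replications with both values defined).
#' @export
se_bias_summary <- function(model_ses, estimates,
                            ci_type = c("percentile", "normal")) {
  ci_type <- match.arg(ci_type)
  keep <- !is.na(model_ses) & !is.na(estimates)
  if (sum(keep) < 2L) stop("need at least 2 defined replications",
                           call. = FALSE)
  emp_se <- sd(estimates[keep])
  if (emp_se <= 0) stop("empirical SE is zero; percent SE bias undefined",
                        call. = FALSE)
  pct <- 100 * (model_ses[keep] - emp_se) / emp_se
  list(empirical_se = emp_se,
       mean_percent_se_bias = mean(pct),
       ci = monte_carlo_ci(pct, type = ci_type),
       n_used = sum(keep))
}

#' Total sample size for a two-sample t-test at a given effect size
#'
#' Smallest even total `N = 2n` such that a two-sided two-sample t-test
#' with `n` subjects per group attains at least the requested power for a
#' standardised effect size `d`, using the exact noncentral-t power
#' (integer search started from the normal approximation).
#'
#' @param d Cohen's standardised effect size (> 0).
#' @param power Target power in (0, 1), default 0.80.
#' @param alpha Two-sided type I error, default 0.05.
#' @return Total sample size across the two equal groups.
#' @examples
#' power_sample_size(0.8)  # 52
#' power_sample_size(0.2)  # 788
#' @export
power_sample_size <- function(d, power = 0.80, alpha = 0.05) {
  if (d <= 0 || power <= 0 || power >= 1 || alpha <= 0 || alpha >= 1) {
    stop("invalid design parameters", call. = FALSE)
  }
  pow <- function(n) {
    power.t.test(n = n, delta = d, sd = 1, sig.level = alpha,
                 type = "two.sample", alternative = "two.sided")$power
  }
  n0 <- 2 * (qnorm(1 - alpha / 2) + qnorm(power))^2 / d^2
  n <- max(2L, floor(n0) - 2L)
  while (pow(n) < power) n <- n + 1L
  2L * as.integer(n)
}

#' Flag clinically important bias of the mean FTND score
#'
#' A mean bias of one point or more on the 0-10 FTND scale (10% of the
#' range, enough to move a subject across dependence categories) is
#' treated as clinically important.
#'
#' @param summary A `PerformanceSummary` data frame (see [run_grid()])
#'   containing `estimand` and `mean_bias` columns.
#' @param threshold Clinical importance threshold in points (default 1).
#' @return The summary with a logical `clinically_important` column, `NA`
#'   for estimands other than the mean FTND score.
#' @export
flag_clinical_bias <- function(summary, threshold = 1) {
  flag <- rep(NA, nrow(summary))
  is_mean <- summary$estimand == "mean_ftnd"
  flag[is_mean] <- abs(summary$mean_bias[is_mean]) >= threshold
  summary$clinically_important <- flag
  summary
}
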