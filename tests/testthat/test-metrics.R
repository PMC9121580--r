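test_that("mean and SE of totals follow the textbook formulas", {
  e <- mean_and_se(c(4, 6))
  expect_equal(e$value, 5)
  expect_equal(e$model_se, 1)  # sd = sqrt(2), sqrt(2)/sqrt(2) = 1
  expect_equal(e$n_used, 2L)

  const <- mean_and_se(rep(3, 10))
  expect_equal(const$value, 3)
  expect_equal(const$model_se, 0)

  with_na <- mean_and_se(c(4, NA, 6))
  expect_equal(with_na$value, 5)
  expect_equal(with_na$model_se, 1)

  undef <- mean_and_se(c(5, NA))
  expect_false(undef$ok)
  expect_true(is.na(undef$value))
})

test_that("the simple OLS slope matches lm() and the two-group identity", {
  y <- c(3, 5, 4, 8); x <- c(0, 0, 1, 1)
  e <- ols_simple(y, x)
  fit <- lm(y ~ x)
  expect_equal(e$value, unname(coef(fit)[2]))
  expect_equal(e$model_se, unname(sqrt(diag(vcov(fit)))[2]))
  # binary x: slope is the difference of group means
  expect_equal(e$value, mean(y[x == 1]) - mean(y[x == 0]))

  exact <- ols_simple(2 * c(1, 2, 3, 4) + 1, c(1, 2, 3, 4))
  expect_equal(exact$value, 2)
  expect_equal(exact$model_se, 0)

  expect_false(ols_simple(c(1, 2, 3), c(1, 1, 1))$ok)
  expect_false(ols_simple(c(1, NA, NA, 2), c(0, 1, 0, 1))$ok)
})

test_that("bias and percent bias are exact arithmetic", {
  b <- bias_and_percent(4.2, 4.7)
  expect_equal(b$bias, -0.5)
  expect_equal(b$percent_bias, 100 * (4.2 - 4.7) / 4.7)

  expect_equal(bias_and_percent(3, 3), list(bias = 0, percent_bias = 0))
  expect_equal(bias_and_percent(6, 3)$percent_bias, 100)

  # identity: percent * theta / 100 + theta recovers theta_hat exactly
  set.seed(11)
  for (i in 1:50) {
    theta <- runif(1, 0.5, 9)
    theta_hat <- runif(1, 0, 10)
    r <- bias_and_percent(theta_hat, theta)
    expect_equal(r$percent_bias * theta / 100 + theta, theta_hat,
                 tolerance = 1e-12)
    expect_equal(r$bias + theta, theta_hat, tolerance = 1e-12)
  }

  tiny <- bias_and_percent(1, 1e-12)
  expect_true(is.na(tiny$percent_bias))
  expect_equal(tiny$bias, 1 - 1e-12)
})

test_that("the Monte Carlo interval matches a sort-based oracle", {
  expect_equal(monte_carlo_ci(rep(4, 10)), c(4, 4))

  x <- as.numeric(1:1000)
  ci <- monte_carlo_ci(x)
  # oracle: linear interpolation between order statistics at h = 1+(n-1)p
  oracle <- function(v, p) {
    v <- sort(v); h <- 1 + (length(v) - 1) * p
    lo <- floor(h)
    v[lo] + (h - lo) * (v[min(lo + 1, length(v))] - v[lo])
  }
  expect_equal(ci, c(oracle(x, 0.025), oracle(x, 0.975)))

  set.seed(21)
  z <- rnorm(500)
  ci2 <- monte_carlo_ci(z)
  expect_equal(ci2, c(oracle(z, 0.025), oracle(z, 0.975)))
  expect_lte(ci2[1], ci2[2])

  sym <- c(-(1:50), 1:50)
  ci3 <- monte_carlo_ci(sym)
  expect_equal(ci3[1], -ci3[2])

  norm_ci <- monte_carlo_ci(z, type = "normal")
  expect_equal(norm_ci, mean(z) + c(-1, 1) * qnorm(0.975) * sd(z))
})

test_that("SE bias compares model SEs to the empirical SE over replications", {
  set.seed(31)
  est <- rnorm(200, 5, 0.4)
  emp <- sd(est)
  same <- se_bias_summary(rep(emp, 200), est)
  expect_equal(same$mean_percent_se_bias, 0)
  expect_equal(same$ci, c(0, 0))

  shrunk <- se_bias_summary(rep(0.65 * emp, 200), est)
  expect_equal(shrunk$mean_percent_se_bias, -35)

  # 5-replication hand case: estimates (4,5,6,5,4), all model SEs 1
  h <- se_bias_summary(rep(1, 5), c(4, 5, 6, 5, 4))
  hand_emp <- sqrt(sum((c(4, 5, 6, 5, 4) - 4.8)^2) / 4)
  expect_equal(h$empirical_se, hand_emp)
  expect_equal(h$mean_percent_se_bias, 100 * (1 - hand_emp) / hand_emp)

  expect_error(se_bias_summary(rep(1, 5), rep(2, 5)), "zero")
})

test_that("power-based sample sizes reproduce the two design sizes", {
  expect_identical(power_sample_size(0.8, 0.80, 0.05), 52L)
  expect_identical(power_sample_size(0.2, 0.80, 0.05), 788L)
})

test_that("sample size is monotone in effect size and near the normal rule", {
  sizes <- vapply(c(0.2, 0.3, 0.5, 0.8, 1.2), power_sample_size, integer(1))
  expect_true(all(diff(sizes) < 0))
  for (d in c(0.2, 0.4, 0.8)) {
    n_norm <- 2 * (qnorm(0.975) + qnorm(0.80))^2 / d^2
    total <- power_sample_size(d)
    expect_gte(total, 2 * floor(n_norm))
    expect_lte(total, 2 * (ceiling(n_norm) + 2))
  }
  expect_error(power_sample_size(-1), "invalid")
})

test_that("clinical-importance flag marks mean-FTND bias of 1+ points", {
  s <- data.frame(estimand = c("mean_ftnd", "mean_ftnd", "mean_ftnd",
                               "regression_coefficient"),
                  mean_bias = c(-0.5, -1.0, 1.3, -1.2))
  f <- flag_clinical_bias(s)
  expect_identical(f$clinically_important, c(FALSE, TRUE, TRUE, NA))
})
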