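test_that("MAR eligibility probabilities follow the logistic model", {
  d <- make_ftnd_data(rep(0, 6), gender = 0L, smoke_where = "no")
  expect_equal(eligibility_probabilities_mar(d, beta0 = 0), 0.5)

  d2 <- make_ftnd_data(rep(0, 6), gender = 1L, smoke_where = "yes_inside")
  # male smoking inside: logistic(0.20 - 1.99) = 1 / (1 + exp(1.79))
  expect_equal(eligibility_probabilities_mar(d2, beta0 = 0),
               1 / (1 + exp(1.79)))
  expect_equal(round(exp(0.20), 2), 1.22)  # published OR for gender

  d3 <- make_ftnd_data(rep(0, 6))
  d3$gender <- NA_integer_
  expect_error(eligibility_probabilities_mar(d3, beta0 = 0), "non-missing")
})

test_that("MNAR eligibility increases with the true total score", {
  expect_equal(eligibility_probabilities_mnar(4.7, beta0 = -0.94,
                                              beta1 = 0.2), 0.5)
  p <- eligibility_probabilities_mnar(c(0, 10), beta0 = 0, beta1 = 0.2)
  expect_equal(p, c(0.5, 1 / (1 + exp(-2))))
  expect_true(all(diff(eligibility_probabilities_mnar(0:10, -1, 0.2)) > 0))
  expect_error(eligibility_probabilities_mnar(c(1, NA), 0), "complete")
})

test_that("the intercept solver hits the target eligibility rate", {
  expect_equal(solve_beta0(rep(0, 100), 0.5), 0, tolerance = 1e-7)
  expect_equal(solve_beta0(rep(0, 50), 0.1), log(0.1 / 0.9),
               tolerance = 1e-6)

  pop <- calibrated_pop()
  cfg <- solve_missingness(pop, missingness_config("MAR", p_sub = 0.3,
                                                   p_item = 0.5))
  probs <- eligibility_probabilities_mar(pop, cfg$beta0)
  expect_lt(abs(mean(probs) - 0.3), 1e-6)

  cfg2 <- solve_missingness(pop, missingness_config("MNAR", p_sub = 0.1,
                                                    p_item = 0.5))
  probs2 <- eligibility_probabilities_mnar(ftnd_total(pop), cfg2$beta0)
  expect_lt(abs(mean(probs2) - 0.1), 1e-6)
})

test_that("degenerate item-deletion probabilities behave as stated", {
  pop <- calibrated_pop()[1:200, ]
  none <- draw_missingness(pop, missingness_config("MAR", 0.5, 0),
                           seed = 8)
  expect_identical(none$observed, pop)

  all_cfg <- missingness_config("MNAR", 0.999, 1)
  all_cfg$beta0 <- 50  # force universal eligibility
  res <- draw_missingness(pop, all_cfg, seed = 9)
  expect_true(all(res$mask$eligible == 1L))
  expect_true(all(is.na(res$observed[, paste0("item", 1:6)])))
})

test_that("masks respect eligibility and reproduce under a seed", {
  pop <- calibrated_pop()[1:1000, ]
  cfg <- missingness_config("MNAR", 0.3, 0.5)
  a <- draw_missingness(pop, cfg, seed = 21)
  b <- draw_missingness(pop, cfg, seed = 21)
  expect_identical(a$observed, b$observed)
  expect_identical(a$mask, b$mask)
  ineligible <- a$mask$eligible == 0L
  expect_true(all(a$mask$deleted[ineligible, ] == 0L))
  expect_identical(dim(a$mask$deleted), c(1000L, 6L))
  # covariates are never deleted
  expect_false(anyNA(a$observed$gender))
  expect_false(anyNA(a$observed$smoking_allowed))
})

test_that("overall missing-cell fraction converges to p_sub * p_item", {
  pop <- calibrated_pop()[1:500, ]
  for (ps in c(0.1, 0.5)) {
    for (pi in c(0.1, 0.7)) {
      cfg <- solve_missingness(pop, missingness_config("MAR", ps, pi))
      fracs <- vapply(1:150, function(i) {
        res <- draw_missingness(pop, cfg, seed = 1000 + i)
        mean(res$mask$deleted)
      }, numeric(1))
      expected <- ps * pi
      mc_sd <- sd(fracs) / sqrt(length(fracs))
      expect_lt(abs(mean(fracs) - expected), 3 * mc_sd + 0.002)
    }
  }
})

test_that("MNAR eligibility selects the more dependent smokers", {
  pop <- calibrated_pop()[1:800, ]
  cfg <- solve_missingness(pop, missingness_config("MNAR", 0.3, 0.5))
  totals <- ftnd_total(pop)
  for (s in 1:20) {
    res <- draw_missingness(pop, cfg, seed = s)
    el <- res$mask$eligible == 1L
    expect_gt(mean(totals[el]), mean(totals[!el]))
  }
})

test_that("the MAR mask ignores item values given the covariates", {
  pop <- calibrated_pop()[1:600, ]
  cfg <- solve_missingness(pop, missingness_config("MAR", 0.3, 0.5))
  # permute item columns within covariate strata before drawing the mask:
  # seed-matched masks must be identical because MAR eligibility only
  # reads the covariates
  strata <- interaction(pop$gender, pop$smoke_where, drop = TRUE)
  permuted <- pop
  set.seed(404)
  for (s in levels(strata)) {
    rows <- which(strata == s)
    permuted[rows, paste0("item", 1:6)] <-
      pop[rows[sample(length(rows))], paste0("item", 1:6)]
  }
  a <- draw_missingness(pop, cfg, seed = 77)
  b <- draw_missingness(permuted, cfg, seed = 77)
  expect_identical(a$mask, b$mask)
})

test_that("missingness configuration validates its probabilities", {
  expect_error(missingness_config("MAR", p_sub = 0, p_item = 0.5), "p_sub")
  expect_error(missingness_config("MAR", p_sub = 1, p_item = 0.5), "p_sub")
  expect_error(missingness_config("MAR", p_sub = 0.5, p_item = 1.2),
               "p_item")
})
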