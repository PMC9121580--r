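test_that("sampling with replacement is uniform, seeded and edge-safe", {
  pop <- calibrated_pop()
  one <- pop[1, , drop = FALSE]
  five <- sample_with_replacement(one, 5, seed = 1)
  expect_identical(nrow(five), 5L)
  expect_true(all(five$id == one$id))

  empty <- sample_with_replacement(pop, 0, seed = 1)
  expect_identical(nrow(empty), 0L)
  expect_error(sample_with_replacement(pop[0, ], 5), "empty")

  a <- sample_with_replacement(pop, 100, seed = 42)
  b <- sample_with_replacement(pop, 100, seed = 42)
  expect_identical(a, b)
})

test_that("the duplicate count matches the closed-form expectation", {
  pop <- calibrated_pop()[1:500, ]
  n_obs <- 200
  dup <- vapply(1:400, function(s) {
    s_ <- sample_with_replacement(pop, n_obs, seed = 10000 + s)
    n_obs - length(unique(s_$id))
  }, numeric(1))
  expected <- n_obs - 500 * (1 - (1 - 1 / 500)^n_obs)
  mc_se <- sd(dup) / sqrt(length(dup))
  expect_lt(abs(mean(dup) - expected), 4 * mc_se)
})

test_that("a replication is a pure function of its cell seed and index", {
  pop <- calibrated_pop()[1:2000, ]
  cell <- list(mechanism = "MNAR", p_sub = 0.3, p_item = 0.5, n_obs = 100,
               seed = 7L)
  a <- run_replication(pop, cell, replication_index = 3)
  b <- run_replication(pop, cell, replication_index = 3)
  expect_identical(a, b)
  c_ <- run_replication(pop, cell, replication_index = 4)
  expect_false(identical(a, c_))
})

test_that("without missingness every method recovers the truth exactly", {
  pop <- calibrated_pop()[1:2000, ]
  cell <- list(mechanism = "MAR", p_sub = 0.5, p_item = 0, n_obs = 150,
               seed = 9L)
  r <- run_replication(pop, cell, 1)
  expect_true(all(r$theta_hat == r$theta))
  expect_true(all(r$ok))
})

test_that("complete subjects score identically across methods in a replication", {
  pop <- calibrated_pop()[1:2000, ]
  cell <- list(mechanism = "MNAR", p_sub = 0.5, p_item = 0.5, n_obs = 120,
               seed = 13L)
  r <- run_replication(pop, cell, 2)
  # the paired design: every method sees the same observed data, so the
  # mean-FTND estimates of full-imputation methods use all subjects
  n_used <- r$n_used[r$estimand == "mean_ftnd"]
  names(n_used) <- r$method[r$estimand == "mean_ftnd"]
  expect_identical(unname(n_used["item_mean"]), 120L)
  expect_identical(unname(n_used["hot_deck"]), 120L)
  expect_lte(n_used["cca"], n_used["drop_one"])
  expect_identical(unname(n_used["proration"]), unname(n_used["hr_item_mean"]))
})

test_that("the default grid has the published cardinality", {
  g <- ftnd_grid()
  expect_identical(nrow(g$cells), 48L)
  expect_identical(nrow(g$cells) * length(g$methods) * 2L, 576L)
})

test_that("run_grid aggregates cells deterministically", {
  pop <- calibrated_pop()[1:3000, ]
  g <- ftnd_grid(n_obs = 80, mechanisms = "MNAR", p_sub = 0.3,
                 p_item = c(0.3, 0.5), replications = 8,
                 methods = c("cca", "proration"), seed = 21)
  sim <- run_grid(pop, g)
  expect_s3_class(sim, "ftnd_sim")
  expect_identical(nrow(sim$summary), 2L * 2L * 2L)
  expect_true(all(c("mean_bias", "mean_percent_bias", "empirical_se",
                    "se_percent_bias", "clinically_important")
                  %in% names(sim$summary)))
  expect_true(all(sim$summary$pct_ci_low <= sim$summary$pct_ci_high))
  sim2 <- run_grid(pop, g)
  sim$manifest$timestamp <- sim2$manifest$timestamp <- NULL
  expect_identical(sim$summary, sim2$summary)

  s <- summary(sim)
  expect_s3_class(s, "summary.ftnd_sim")
  expect_identical(nrow(s$measures$percent_bias_mean_ftnd), 2L)
  expect_output(print(s), "method ranking")
})

test_that("single-replication grids are flagged as undefined, not fatal", {
  pop <- calibrated_pop()[1:1000, ]
  g <- ftnd_grid(n_obs = 60, mechanisms = "MAR", p_sub = 0.3, p_item = 0.3,
                 replications = 1, methods = "cca", seed = 2)
  w <- capture_warnings(sim <- run_grid(pop, g))
  expect_match(w, "fewer than 2 defined replications", all = TRUE)
  expect_length(w, 2)  # one per estimand
  expect_true(all(is.na(sim$summary$mean_percent_bias)))
  expect_identical(sim$summary$n_reps, rep(1L, 2))
})
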