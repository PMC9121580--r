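na <- NA_integer_

test_that("Gower's distance matches hand-worked values and its bounds", {
  a <- list(gender = 0L, smoking_allowed = 0L, item1 = 2L)
  b <- list(gender = 0L, smoking_allowed = 1L, item1 = 3L)
  vars <- c("gender", "smoking_allowed", "item1")
  expect_equal(gower_distance(a, b, vars), (0 + 1 + 1 / 3) / 3)
  expect_equal(gower_distance(a, a, vars), 0)
  worst <- list(gender = 1L, smoking_allowed = 1L, item1 = 5L - 5L)
  worst$item1 <- 0L; a$item1 <- 3L
  expect_equal(gower_distance(a, worst, vars), 1)
  expect_error(gower_distance(a, list(gender = NA, smoking_allowed = 1,
                                      item1 = 1), vars), "missing")
})

test_that("an exactly matching donor is always in the nearest-k pool", {
  # donor 2 matches the recipient on every distance variable
  d <- make_ftnd_data(c(na, 1, 1, 2, 0, 1,
                        3,  1, 1, 2, 0, 1,
                        0,  0, 0, 0, 1, 0,
                        1,  0, 1, 1, 1, 0,
                        2,  1, 0, 0, 0, 1,
                        3,  0, 0, 1, 0, 0,
                        1,  1, 1, 2, 1, 1),
                      smoking_allowed = c(1, 1, 0, 0, 0, 0, 0))
  hits <- vapply(1:200, function(s) {
    score_hot_deck(d, k = 1, seed = s)$imputed[1, "item1"]
  }, numeric(1))
  expect_true(all(hits == 3))  # the zero-distance donor always donates
})

test_that("the donor is drawn uniformly from the k nearest candidates", {
  # recipient missing items 1 and 6; donors 2..6 sit at distinct positive
  # distances (over gender, smoking_allowed, items 2-5) and carry distinct
  # (item1, item6) pairs, so the donated pair identifies the donor; donor 7
  # is far on every variable and must never be drawn with k = 5
  d <- make_ftnd_data(c(na, 1, 1, 2, 1, na,
                        3,  1, 1, 2, 1, 1,   # d = 0
                        2,  1, 1, 1, 1, 0,   # d = 1/18
                        3,  1, 1, 0, 1, 0,   # d = 1/9
                        1,  0, 1, 2, 1, 1,   # d = 1/6
                        0,  1, 0, 2, 0, 0,   # d = 1/3
                        2,  0, 0, 0, 0, 1),  # farthest: excluded
                      gender = c(0, 0, 0, 0, 0, 0, 1),
                      smoking_allowed = c(1, 1, 1, 1, 1, 1, 0))
  pair_of <- function(s) {
    imp <- score_hot_deck(d, k = 5, seed = s)$imputed
    paste(imp[1, "item1"], imp[1, "item6"])
  }
  draws <- vapply(1:5000, pair_of, character(1))
  counts <- table(draws)
  expect_identical(length(counts), 5L)  # donor 7 never donates
  # chi-square goodness of fit against the uniform draw over 5 donors
  expect_gt(chisq.test(as.vector(counts))$p.value, 0.001)
})

test_that("nearest-k pools match an exhaustive all-pairs oracle", {
  set.seed(812)
  ranges <- c(3, 1, 1, 3, 1, 1)
  for (trial in 1:15) {
    n <- sample(5:8, 1)
    items <- sapply(1:6, function(j) sample(0:ranges[j], n, replace = TRUE))
    recipient <- 1L
    m_set <- sort(sample(1:6, sample(1:2, 1)))
    items[recipient, m_set] <- NA
    d <- make_ftnd_data(rep(0L, n * 6L),
                        gender = sample(0:1, n, replace = TRUE),
                        smoking_allowed = sample(0:1, n, replace = TRUE))
    d[, paste0("item", 1:6)] <- items
    o_set <- setdiff(1:6, m_set)
    vars <- c("gender", "smoking_allowed", paste0("item", o_set))
    cand <- setdiff(which(rowSums(is.na(items)) == 0L), recipient)
    dist <- vapply(cand, function(i) {
      gower_distance(d[recipient, ], d[i, ], vars)
    }, numeric(1))
    k <- min(3L, length(cand))
    kth <- sort(dist)[k]
    oracle_pool <- cand[dist <= kth + 1e-9]
    suppressWarnings({
      donated <- vapply(1:40, function(s) {
        score_hot_deck(d, k = 3, seed = s)$imputed[recipient, m_set[1]]
      }, numeric(1))
    })
    oracle_values <- items[oracle_pool, m_set[1]]
    expect_true(all(donated %in% oracle_values))
  }
})

test_that("hot-deck totals are integer and imputations come from donors", {
  pop <- calibrated_pop()[1:300, ]
  obs <- draw_missingness(pop, missingness_config("MNAR", 0.5, 0.5),
                          seed = 91)$observed
  r <- score_hot_deck(obs, seed = 92)
  expect_true(all(r$total == round(r$total)))
  expect_false(anyNA(r$total))
  items <- as.matrix(obs[, paste0("item", 1:6)])
  for (j in 1:6) {
    imp <- r$imputed[, j]
    filled <- imp[!is.na(imp)]
    observed_values <- items[!is.na(items[, j]), j]
    expect_true(all(filled %in% observed_values))
  }
})

test_that("identical seeds give identical hot-deck imputations", {
  pop <- calibrated_pop()[1:150, ]
  obs <- draw_missingness(pop, missingness_config("MAR", 0.5, 0.5),
                          seed = 14)$observed
  a <- score_hot_deck(obs, seed = 3)
  b <- score_hot_deck(obs, seed = 3)
  expect_identical(a, b)
})

test_that("donor-pool shortfall warns by default and errors in strict mode", {
  d <- make_ftnd_data(c(na, 1, 1, 2, 0, 1,
                        3, 1, 1, 2, 0, 1,
                        2, 0, 1, 1, 1, 0))
  expect_warning(score_hot_deck(d, k = 5, seed = 1), "fewer than k")
  expect_error(score_hot_deck(d, k = 5, seed = 1, strict = TRUE),
               "candidate donors")
})
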