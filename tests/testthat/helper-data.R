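# Small dataset builders used across tests.  All fixtures are constructed
# in code; item columns may contain NA to represent skipped items.

make_ftnd_data <- function(items, gender = NULL, smoke_where = NULL,
                           smoking_allowed = NULL) {
  items <- matrix(as.integer(items), ncol = 6L, byrow = TRUE,
                  dimnames = list(NULL, paste0("item", 1:6)))
  n <- nrow(items)
  if (is.null(gender)) gender <- rep(0L, n)
  if (is.null(smoke_where)) smoke_where <- rep("no", n)
  if (is.null(smoking_allowed)) smoking_allowed <- rep(0L, n)
  data.frame(id = seq_len(n), items, gender = gender,
             smoke_where = factor(smoke_where,
                                  levels = c("no", "yes_outside",
                                             "yes_inside")),
             smoking_allowed = smoking_allowed)
}

# A complete 8-subject dataset with varied covariates and item scores.
toy_complete <- function() {
  make_ftnd_data(
    c(3, 1, 1, 2, 0, 1,
      2, 0, 1, 1, 1, 0,
      0, 0, 0, 0, 0, 0,
      1, 1, 0, 3, 0, 1,
      2, 1, 1, 2, 1, 1,
      3, 0, 1, 1, 0, 0,
      1, 0, 0, 2, 1, 1,
      2, 1, 0, 0, 0, 1),
    gender = c(0, 1, 0, 1, 0, 1, 0, 1),
    smoke_where = c("no", "yes_outside", "yes_inside", "no",
                    "yes_outside", "no", "yes_inside", "no"),
    smoking_allowed = c(0, 1, 1, 0, 1, 0, 0, 1))
}

# Independent mid-rank Spearman correlation: rank by brute-force midranks,
# then the Pearson formula on the ranks.
brute_spearman <- function(x, y) {
  midrank <- function(v) {
    vapply(seq_along(v), function(i) {
      sum(v < v[i]) + (1 + sum(v == v[i])) / 2
    }, numeric(1))
  }
  rx <- midrank(x); ry <- midrank(y)
  sum((rx - mean(rx)) * (ry - mean(ry))) /
    sqrt(sum((rx - mean(rx))^2) * sum((ry - mean(ry))^2))
}

# Shared medium-sized calibrated population, built once per test run.
calibrated_pop <- local({
  cache <- NULL
  function(n = 20000L, seed = 4821L) {
    if (is.null(cache)) {
      cache <<- generate_population(ftnd_generator(seed = seed), n = n)
    }
    cache
  }
})
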