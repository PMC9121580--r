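#' Simulation grid definition
#'
#' Describes the full factorial simulation design: sample sizes drawn with
#' replacement from the synthetic population, missingness mechanisms, the
#' subject- and item-level missingness probabilities, the number of Monte
#' Carlo replications per cell, and the scoring methods compared.  The
#' default grid is 2 sample sizes x 2 mechanisms x 3 `p_sub` x 4 `p_item`
#' = 48 cells with 1000 replications each.
#'
#' @param n_obs Sample sizes (default `c(52, 788)`, the sizes powered for
#'   Cohen's d of 0.8 and 0.2; see [power_sample_size()]).
#' @param mechanisms Subset of `c("MAR", "MNAR")`.
#' @param p_sub Subject-eligibility proportions (default 0.1, 0.3, 0.5).
#' @param p_item Item-deletion probabilities (default 0.1, 0.3, 0.5, 0.7).
#' @param replications Monte Carlo replications per cell (default 1000).
#' @param methods Scoring methods to compare (default all six).
#' @param k Hot-deck donor pool size.
#' @param seed Master seed for the whole grid.
#' @param ci_type Monte Carlo interval type, `"percentile"` or `"normal"`.
#' @return An object of class `ftnd_grid`.
#' @export
ftnd_grid <- function(n_obs = c(52L, 788L),
                      mechanisms = c("MAR", "MNAR"),
                      p_sub = c(0.1, 0.3, 0.5),
                      p_item = c(0.1, 0.3, 0.5, 0.7),
                      replications = 1000L,
                      methods = ftnd_methods(),
                      k = 5L,
                      seed = 1L,
                      ci_type = c("percentile", "normal")) {
  mechanisms <- match.arg(mechanisms, c("MAR", "MNAR"), several.ok = TRUE)
  methods <- match.arg(methods, ftnd_methods(), several.ok = TRUE)
  ci_type <- match.arg(ci_type)
  if (replications < 1L) stop("`replications` must be >= 1", call. = FALSE)
  cells <- expand.grid(mechanism = mechanisms, p_sub = p_sub,
                       p_item = p_item, n_obs = as.integer(n_obs),
                       KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  if (nrow(cells) == 0L) stop("grid is empty", call. = FALSE)
  structure(list(cells = cells, replications = as.integer(replications),
                 methods = methods, k = as.integer(k),
                 seed = as.integer(seed), ci_type = ci_type),
            class = "ftnd_grid")
}

#' Sample subjects with replacement from a population
#'
#' @param population Non-empty complete dataset.
#' @param n_obs Number of rows to draw (0 gives an empty dataset).
#' @param seed Optional integer seed.
#' @return A dataset of `n_obs` rows drawn uniformly with replacement.
#' @export
sample_with_replacement <- function(population, n_obs, seed = NULL) {
  if (nrow(population) == 0L) stop("`population` is empty", call. = FALSE)
  idx <- with_seed(seed, sample.int(nrow(population), n_obs, replace = TRUE))
  out <- population[idx, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Run one simulation replication of one grid cell
#'
#' Draws a sample of `n_obs` subjects with replacement, records the true
#' mean FTND and regression slope on the complete sample, solves the
#' eligibility intercept for the sample, injects missingness, scores the
#' observed data with every requested method (all methods see the
#' identical observed dataset), and estimates both estimands per method.
#'
#' @param population Complete synthetic population.
#' @param cell A list with `mechanism`, `p_sub`, `p_item`, `n_obs`, and
#'   optionally `methods`, `k` and `seed` (the cell-level seed).
#' @param replication_index Replication number; combined with the cell
#'   seed it fixes every random draw of the replication.
#' @return A data frame with one row per method x estimand: columns
#'   `method`, `estimand`, `theta_hat`, `model_se`, `theta`, `n_used`,
#'   `ok`.
#' @export
run_replication <- function(population, cell, replication_index = 1L) {
  methods <- if (is.null(cell$methods)) ftnd_methods() else cell$methods
  k <- if (is.null(cell$k)) 5L else cell$k
  cell_seed <- if (is.null(cell$seed)) 1L else cell$seed
  rep_seed <- derive_seed(cell_seed, replication_index)
  with_seed(rep_seed, {
    samp <- sample_with_replacement(population, cell$n_obs)
    true_totals <- ftnd_totals(samp)
    truth <- list(mean_ftnd = mean(true_totals),
                  regression_coefficient =
                    ols_simple(true_totals, samp$smoking_allowed)$value)
    config <- missingness_config(mechanism = cell$mechanism,
                                 p_sub = cell$p_sub, p_item = cell$p_item)
    drawn <- draw_missingness(samp, solve_missingness(samp, config))
    results <- score_all_methods(drawn$observed, k = k, methods = methods)
    rows <- lapply(methods, function(m) {
      totals <- results[[m]]$total
      ests <- list(mean_and_se(totals),
                   ols_simple(totals, samp$smoking_allowed))
      do.call(rbind, lapply(ests, function(e) {
        data.frame(method = m, estimand = e$estimand,
                   theta_hat = e$value, model_se = e$model_se,
                   theta = truth[[e$estimand]], n_used = e$n_used,
                   ok = e$ok && is.finite(truth[[e$estimand]]),
                   stringsAsFactors = FALSE)
      }))
    })
    do.call(rbind, rows)
  })
}

#' Run the full simulation grid
#'
#' Executes `replications` Monte Carlo replications for every grid cell
#' and aggregates the performance measures per (mechanism, `p_sub`,
#' `p_item`, `n_obs`, method, estimand): mean bias, mean percent bias with
#' its Monte Carlo 95\% interval, the empirical SE (SD of the estimates
#' over replications), the mean model SE, and the percent SE bias with its
#' interval.  Replications where a method leaves fewer than two usable
#' totals are counted as undefined and excluded from that cell's
#' summaries.
#'
#' @param population Complete synthetic population (see
#'   [generate_population()]).
#' @param grid An [ftnd_grid()].
#' @param progress Print one line per completed cell (default `FALSE`).
#' @return An object of class `ftnd_sim`: list with `summary` (the tidy
#'   performance table, one row per cell x method x estimand), `grid`, and
#'   `manifest` (seeds and versions).
#' @export
run_grid <- function(population, grid = ftnd_grid(), progress = FALSE) {
  if (!inherits(grid, "ftnd_grid")) stop("`grid` must come from ftnd_grid()",
                                         call. = FALSE)
  cells <- grid$cells
  n_cells <- nrow(cells)
  cell_seeds <- with_seed(grid$seed,
                          sample.int(2147483000L, n_cells))
  out <- vector("list", n_cells)
  for (ci in seq_len(n_cells)) {
    cell <- list(mechanism = cells$mechanism[ci], p_sub = cells$p_sub[ci],
                 p_item = cells$p_item[ci], n_obs = cells$n_obs[ci],
                 methods = grid$methods, k = grid$k, seed = cell_seeds[ci])
    reps <- lapply(seq_len(grid$replications), function(r) {
      run_replication(population, cell, r)
    })
    est <- do.call(rbind, reps)
    out[[ci]] <- aggregate_cell(est, cell, grid)
    if (progress) {
      message(sprintf("[%d/%d] %s p_sub=%.1f p_item=%.1f n_obs=%d done",
                      ci, n_cells, cell$mechanism, cell$p_sub, cell$p_item,
                      cell$n_obs))
    }
  }
  summary <- flag_clinical_bias(do.call(rbind, out))
  rownames(summary) <- NULL
  manifest <- list(master_seed = grid$seed, cell_seeds = cell_seeds,
                   replications = grid$replications,
                   methods = grid$methods,
                   package_version = as.character(utils::packageVersion("ftndmiss")),
                   r_version = R.version.string,
                   timestamp = format(Sys.time(), tz = "UTC"))
  structure(list(summary = summary, grid = grid, manifest = manifest),
            class = "ftnd_sim")
}

# Aggregate one cell's replication-level estimates into summary rows.
aggregate_cell <- function(est, cell, grid) {
  combos <- expand.grid(method = grid$methods,
                        estimand = c("mean_ftnd", "regression_coefficient"),
                        KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  rows <- lapply(seq_len(nrow(combos)), function(i) {
    m <- combos$method[i]; e <- combos$estimand[i]
    sub <- est[est$method == m & est$estimand == e, , drop = FALSE]
    ok <- sub$ok & !is.na(sub$theta_hat)
    base <- data.frame(mechanism = cell$mechanism, p_sub = cell$p_sub,
                       p_item = cell$p_item, n_obs = cell$n_obs,
                       method = m, estimand = e,
                       n_reps = nrow(sub), n_undefined = sum(!ok),
                       stringsAsFactors = FALSE)
    if (sum(ok) < 2L) {
      warning("cell ", cell$mechanism, "/", cell$p_sub, "/", cell$p_item,
              " method ", m, ": fewer than 2 defined replications",
              call. = FALSE)
      return(cbind(base, mean_bias = NA_real_, mean_percent_bias = NA_real_,
                   pct_ci_low = NA_real_, pct_ci_high = NA_real_,
                   empirical_se = NA_real_, mean_model_se = NA_real_,
                   se_percent_bias = NA_real_, se_pct_ci_low = NA_real_,
                   se_pct_ci_high = NA_real_))
    }
    bias <- sub$theta_hat[ok] - sub$theta[ok]
    pct <- ifelse(abs(sub$theta[ok]) > 1e-8, 100 * bias / sub$theta[ok],
                  NA_real_)
    pct_ci <- monte_carlo_ci(pct, type = grid$ci_type)
    seb <- se_bias_summary(sub$model_se[ok], sub$theta_hat[ok],
                           ci_type = grid$ci_type)
    cbind(base, mean_bias = mean(bias),
          mean_percent_bias = mean(pct, na.rm = TRUE),
          pct_ci_low = pct_ci[1], pct_ci_high = pct_ci[2],
          empirical_se = seb$empirical_se,
          mean_model_se = mean(sub$model_se[ok]),
          se_percent_bias = seb$mean_percent_se_bias,
          se_pct_ci_low = seb$ci[1], se_pct_ci_high = seb$ci[2])
  })
  do.call(rbind, rows)
}
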