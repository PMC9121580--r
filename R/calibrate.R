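#' Published descriptive targets for generator calibration
#'
#' The calibration targets are the printed descriptive statistics of the
#' helpline FTND sample: per-item means and SDs, total-score mean 4.7 and
#' SD 2.3, Cronbach's alpha 0.59, and the six item-rest Spearman rank
#' correlations.  Tolerances default to half a printed decimal for moments
#' (0.05), 0.02 for alpha and 0.05 for rank correlations.
#'
#' Printed values are rounded to one decimal, so they need not be mutually
#' consistent as exact moments (a binary item's SD is determined by its
#' mean, and alpha links the item variances to the total variance).
#' [calibrate_generator()] therefore treats each printed value as the centre
#' of a rounding band and resolves the moments jointly within the stated
#' tolerances.
#'
#' @param item_means,item_sds Length-6 numeric targets per item.
#' @param total_mean,total_sd Targets for the total score (0-10 scale).
#' @param cronbach_alpha Target internal consistency.
#' @param item_rest_correlations Length-6 Spearman item-rest targets.
#' @param tolerances Named list of per-target tolerances (all positive):
#'   `item_mean`, `item_sd`, `total_mean`, `total_sd`, `alpha`, `item_rest`.
#' @return An object of class `ftnd_targets`.
#' @export
ftnd_targets <- function(item_means = c(2.0, 0.3, 0.6, 0.9, 0.4, 0.5),
                         item_sds = c(1.0, 0.4, 0.5, 0.8, 0.5, 0.5),
                         total_mean = 4.7,
                         total_sd = 2.3,
                         cronbach_alpha = 0.59,
                         item_rest_correlations = c(0.48, 0.26, 0.35,
                                                    0.36, 0.31, 0.31),
                         tolerances = list(item_mean = 0.05, item_sd = 0.05,
                                           total_mean = 0.05, total_sd = 0.05,
                                           alpha = 0.02, item_rest = 0.05)) {
  stopifnot(length(item_means) == 6L, length(item_sds) == 6L,
            length(item_rest_correlations) == 6L)
  vals <- c(item_means, item_sds, total_mean, total_sd, cronbach_alpha,
            item_rest_correlations, unlist(tolerances))
  if (any(!is.finite(vals))) stop("all targets must be finite", call. = FALSE)
  if (any(unlist(tolerances) <= 0)) {
    stop("tolerances must be positive", call. = FALSE)
  }
  if (abs(total_mean - sum(item_means)) > 0.5) {
    stop("`total_mean` inconsistent with the sum of `item_means`",
         call. = FALSE)
  }
  structure(list(item_means = item_means, item_sds = item_sds,
                 total_mean = total_mean, total_sd = total_sd,
                 cronbach_alpha = cronbach_alpha,
                 item_rest_correlations = item_rest_correlations,
                 tolerances = tolerances),
            class = "ftnd_targets")
}

# Moments of a discrete distribution on scores 0..(k-1).
disc_moments <- function(probs) {
  s <- seq_along(probs) - 1
  m <- sum(probs * s)
  list(mean = m, sd = sqrt(sum(probs * (s - m)^2)))
}

# Category probabilities on {0,1,2,3} from a normal discretised at
# 0.5/1.5/2.5, fitted to a target mean and SD.
fit_ordinal_probs <- function(target_mean, target_sd) {
  probs_of <- function(par) {
    a <- par[1]; b <- exp(par[2])
    diff(c(0, pnorm((c(0.5, 1.5, 2.5) - a) / b), 1))
  }
  obj <- function(par) {
    mo <- disc_moments(probs_of(par))
    (mo$mean - target_mean)^2 + (mo$sd - target_sd)^2
  }
  fit <- optim(c(target_mean, log(max(target_sd, 0.2))), obj,
               method = "Nelder-Mead",
               control = list(maxit = 2000, reltol = 1e-14))
  p <- probs_of(fit$par)
  if (obj(fit$par) > 1e-6) {
    stop("cannot match an ordinal item marginal to mean ",
         signif(target_mean, 3), ", SD ", signif(target_sd, 3), call. = FALSE)
  }
  p
}

# Resolve the printed marginal targets into exact per-item category
# probabilities that are jointly consistent with the total-mean, total-SD
# and alpha targets.  Returns list(probs, means, sds).
resolve_marginals <- function(targets) {
  tol <- targets$tolerances
  k6 <- 1:6
  binary <- c(2L, 3L, 5L, 6L)
  ordinal <- c(1L, 4L)
  means <- targets$item_means
  sds <- targets$item_sds

  # Binary items: SD is a function of the mean.  If the implied SD leaves
  # the SD band, nudge the mean (within its own band) to the nearest
  # feasible value, keeping a 5% safety margin inside each band.
  for (j in binary) {
    m <- means[j]
    implied <- sqrt(m * (1 - m))
    if (abs(implied - sds[j]) > tol$item_sd) {
      s_edge <- if (implied > sds[j]) sds[j] + 0.95 * tol$item_sd
                else sds[j] - 0.95 * tol$item_sd
      disc <- 1 - 4 * s_edge^2
      if (disc < 0) disc <- 0
      root <- c((1 - sqrt(disc)) / 2, (1 + sqrt(disc)) / 2)
      m_new <- root[which.min(abs(root - m))]
      if (abs(m_new - means[j]) > tol$item_mean) {
        stop("binary item ", j, ": printed mean and SD are irreconcilable ",
             "within tolerances", call. = FALSE)
      }
      means[j] <- m_new
    }
    sds[j] <- sqrt(means[j] * (1 - means[j]))
  }

  # Re-centre the ordinal-item means so item means sum to the total mean.
  deficit <- targets$total_mean - sum(means)
  shift <- deficit / length(ordinal)
  shift <- sign(shift) * min(abs(shift), 0.95 * tol$item_mean)
  means[ordinal] <- means[ordinal] + shift

  # Alpha ties the sum of item variances to the total variance:
  # sum(var_i) = var_total * (1 - alpha * (k-1)/k).  Give the ordinal items
  # the variance left over after the binary items, split in proportion to
  # their printed variances.
  var_needed <- targets$total_sd^2 * (1 - targets$cronbach_alpha * 5 / 6)
  var_left <- var_needed - sum(sds[binary]^2)
  w <- targets$item_sds[ordinal]^2
  v_ord <- var_left * w / sum(w)
  for (i in seq_along(ordinal)) {
    j <- ordinal[i]
    s_new <- sqrt(max(v_ord[i], 1e-4))
    s_new <- min(max(s_new, sds[j] - 0.95 * tol$item_sd),
                 sds[j] + 0.95 * tol$item_sd)
    sds[j] <- s_new
  }

  probs <- vector("list", 6L)
  for (j in k6) {
    probs[[j]] <- if (j %in% binary) c(1 - means[j], means[j])
                  else fit_ordinal_probs(means[j], sds[j])
  }
  mom <- lapply(probs, disc_moments)
  list(probs = probs,
       means = vapply(mom, `[[`, numeric(1), "mean"),
       sds = vapply(mom, `[[`, numeric(1), "sd"))
}

# Simulated dependence moments of a config: alpha and item-rest Spearman.
sim_dependence <- function(config, n, seed) {
  pop <- generate_population(config, n = n, seed = seed)
  items <- ftnd_items(pop)
  list(alpha = cronbach_alpha(items),
       rho = vapply(1:6, function(j) spearman_item_rest(items, j),
                    numeric(1)),
       totals = rowSums(items))
}

#' Calibrate the synthetic-population generator to descriptive targets
#'
#' Fits the latent-trait generator so a large simulated population
#' reproduces the target item marginals, total-score moments, Cronbach's
#' alpha and item-rest rank correlations within their tolerances.  The
#' search is deterministic given `seed` and `search_budget`.
#'
#' The marginal side is handled analytically: category probabilities are
#' resolved from the printed means/SDs (see [ftnd_targets()] for how
#' rounding bands are used), and item thresholds are then solved exactly
#' from the latent-variable mixture CDF at every step, so item means and
#' SDs track their targets regardless of the loadings.  The dependence side
#' is a coordinate search: each round simulates a large population, updates
#' each loading multiplicatively towards its item-rest correlation target,
#' and applies a global loading scale correction towards the alpha target.
#'
#' @param targets An [ftnd_targets()] object.
#' @param search_budget Maximum number of search rounds (default 40).
#' @param seed Integer seed controlling every simulation in the search.
#' @param calibration_n Population size used for the final verification
#'   (at least 1e5 recommended); search rounds use `min(calibration_n, 5e4)`.
#' @param covariates Covariate parameters, fixed during the search.
#' @param population_size Population size stored in the returned config.
#' @param start Optional `ftnd_generator` supplying starting loadings.
#' @return A calibrated [ftnd_generator()]; attribute `"calibration"` holds
#'   the achieved moments, the targets and the number of rounds used.
#'   Failure to meet every tolerance within the budget is an error naming
#'   the worst offending target.
#' @export
calibrate_generator <- function(targets = ftnd_targets(),
                                search_budget = 40L,
                                seed = 1L,
                                calibration_n = 100000L,
                                covariates = ftnd_covariates(),
                                population_size = 38334L,
                                start = NULL) {
  if (!inherits(targets, "ftnd_targets")) {
    stop("`targets` must come from ftnd_targets()", call. = FALSE)
  }
  tol <- targets$tolerances
  marg <- resolve_marginals(targets)
  loadings <- if (!is.null(start)) start$loadings
              else pmax(0.3, 2.2 * targets$item_rest_correlations)
  n_search <- as.integer(min(calibration_n, 50000L))

  make_config <- function(lo) {
    thresholds <- lapply(1:6, function(j) {
      solve_thresholds(marg$probs[[j]], lo[j], covariates)
    })
    ftnd_generator(population_size = population_size, loadings = lo,
                   thresholds = thresholds, covariates = covariates)
  }

  rounds <- 0L
  for (r in seq_len(search_budget)) {
    rounds <- r
    cfg <- make_config(loadings)
    dep <- sim_dependence(cfg, n_search, derive_seed(seed, r))
    rho_off <- dep$rho - targets$item_rest_correlations
    alpha_off <- dep$alpha - targets$cronbach_alpha
    if (all(abs(rho_off) < 0.7 * tol$item_rest) &&
        abs(alpha_off) < 0.6 * tol$alpha) break
    fac <- (targets$item_rest_correlations / pmax(dep$rho, 0.02))^0.8
    loadings <- loadings * pmin(pmax(fac, 0.6), 1.6)
    g <- (targets$cronbach_alpha / max(dep$alpha, 0.05))^0.4
    loadings <- loadings * min(max(g, 0.85), 1.2)
  }

  cfg <- make_config(loadings)
  check <- generate_population(cfg, n = calibration_n,
                               seed = derive_seed(seed, 0L))
  items <- ftnd_items(check)
  totals <- rowSums(items)
  achieved <- list(
    item_means = colMeans(items),
    item_sds = apply(items, 2, sd),
    total_mean = mean(totals),
    total_sd = sd(totals),
    cronbach_alpha = cronbach_alpha(items),
    item_rest_correlations = vapply(1:6, function(j) {
      spearman_item_rest(items, j)
    }, numeric(1)),
    dependence_categories = dependence_categories(totals))

  dev <- c(
    abs(achieved$item_means - targets$item_means) / tol$item_mean,
    abs(achieved$item_sds - targets$item_sds) / tol$item_sd,
    abs(achieved$total_mean - targets$total_mean) / tol$total_mean,
    abs(achieved$total_sd - targets$total_sd) / tol$total_sd,
    abs(achieved$cronbach_alpha - targets$cronbach_alpha) / tol$alpha,
    abs(achieved$item_rest_correlations - targets$item_rest_correlations) /
      tol$item_rest)
  names(dev) <- c(paste0("item_mean_", 1:6), paste0("item_sd_", 1:6),
                  "total_mean", "total_sd", "alpha",
                  paste0("item_rest_", 1:6))
  worst <- which.max(dev)
  if (dev[worst] > 1) {
    stop("calibration failed within budget: worst offender `",
         names(dev)[worst], "` off by ", signif(dev[worst], 3),
         "x its tolerance", call. = FALSE)
  }
  attr(cfg, "calibration") <- list(targets = targets, achieved = achieved,
                                   deviations = dev, iterations = rounds,
                                   population_size = calibration_n)
  cfg
}

#' Dependence-category proportions of total FTND scores
#'
#' Classifies totals into the standard bands (0-2 very low, 3-4 low,
#' 5 medium, 6-7 high, 8-10 very high) and returns the proportion in each.
#'
#' @param totals Numeric vector of total scores (missing values dropped).
#' @return Named numeric vector of 5 proportions summing to 1.
#' @export
dependence_categories <- function(totals) {
  totals <- totals[!is.na(totals)]
  cuts <- cut(totals, breaks = c(-0.5, 2.5, 4.5, 5.5, 7.5, 10.5),
              labels = c("very_low", "low", "medium", "high", "very_high"))
  prop.table(table(cuts))
}
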