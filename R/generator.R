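#' Covariate model parameters for the synthetic FTND population
#'
#' Assembles the parameters controlling the three background covariates of
#' the generator: gender, the three-level "If you smoke at home, where?"
#' variable, and the binary "Is smoking allowed in your home?" variable.
#' Gender and smoke-where are drawn independently and shift the latent
#' nicotine-dependence trait by the configured effects; smoking-allowed is
#' drawn conditionally on the trait through a logistic model, which gives it
#' a positive association with the total FTND score.
#'
#' The default effect sizes for gender and smoke-where are deliberately tiny:
#' in a helpline-sized sample such associations are statistically detectable
#' yet practically negligible, and the missing-at-random mechanism built on
#' these covariates then perturbs the FTND distribution only weakly.  The
#' smoking-allowed parameters are calibrated so that the simple-regression
#' coefficient of the total score on smoking-allowed is about 0.7 points in
#' the default population.
#'
#' @param p_male Probability of male gender (default 0.43, i.e. 57% female).
#' @param p_smoke_where Named probabilities of the three smoke-where levels
#'   `no`, `yes_outside`, `yes_inside`; must sum to 1.
#' @param gender_effect Latent-trait shift for males, in trait SD units.
#' @param smoke_where_effect Named trait shifts per smoke-where level.
#' @param smoking_allowed_intercept,smoking_allowed_slope Intercept and slope
#'   of the logistic model Pr(smoking allowed = 1) = plogis(a0 + a1 * trait).
#' @return A list of class `ftnd_covariates`.
#' @export
ftnd_covariates <- function(p_male = 0.43,
                            p_smoke_where = c(no = 0.45,
                                              yes_outside = 0.35,
                                              yes_inside = 0.20),
                            gender_effect = 0.01,
                            smoke_where_effect = c(no = -0.012,
                                                   yes_outside = 0.012,
                                                   yes_inside = 0.02),
                            smoking_allowed_intercept = -0.55,
                            smoking_allowed_slope = 0.38) {
  stopifnot_prob(p_male, "p_male")
  stopifnot_prob(p_smoke_where, "p_smoke_where")
  if (length(p_smoke_where) != 3L ||
      abs(sum(p_smoke_where) - 1) > 1e-12) {
    stop("`p_smoke_where` must be 3 probabilities summing to 1", call. = FALSE)
  }
  if (length(smoke_where_effect) != 3L) {
    stop("`smoke_where_effect` must have 3 elements", call. = FALSE)
  }
  structure(list(p_male = p_male,
                 p_smoke_where = unname(p_smoke_where),
                 gender_effect = gender_effect,
                 smoke_where_effect = unname(smoke_where_effect),
                 smoking_allowed_intercept = smoking_allowed_intercept,
                 smoking_allowed_slope = smoking_allowed_slope),
            class = "ftnd_covariates")
}

#' Synthetic FTND population generator configuration
#'
#' Defines the latent-trait data-generating model for complete six-item FTND
#' responses.  Each subject carries a standard-normal latent nicotine
#' dependence trait shifted by small covariate effects; item `j` is an
#' ordinal threshold discretisation of `loadings[j] * trait + noise` with
#' independent standard-normal noise.  Items 1 and 4 have three thresholds
#' (scores 0-3); items 2, 3, 5 and 6 have one (scores 0/1).
#'
#' The default `loadings` and `thresholds` are the package's calibrated
#' values: they reproduce the published descriptive statistics of the
#' Arizona Smokers' Helpline FTND sample (item means/SDs, total mean 4.7 and
#' SD 2.3, Cronbach's alpha 0.59, and moderate item-rest rank correlations).
#' See [calibrate_generator()] for how such values are obtained.
#'
#' @param population_size Number of subjects generated by default (38,334,
#'   the size of the complete-responder helpline sample being emulated).
#' @param loadings Non-negative discrimination per item (length 6).
#' @param thresholds List of 6 strictly increasing numeric vectors of
#'   cut-points on the latent item scale (3 cut-points for items 1 and 4,
#'   1 for the binary items).
#' @param covariates A [ftnd_covariates()] parameter list.
#' @param seed Optional integer seed stored with the configuration and used
#'   by [generate_population()] when no explicit seed is given.
#' @return An object of class `ftnd_generator`.
#' @seealso [generate_population()], [calibrate_generator()]
#' @examples
#' cfg <- ftnd_generator(population_size = 500, seed = 1)
#' pop <- generate_population(cfg)
#' mean(ftnd_total(pop))
#' @export
ftnd_generator <- function(population_size = 38334L,
                           loadings = ftnd_calibrated_defaults()$loadings,
                           thresholds = ftnd_calibrated_defaults()$thresholds,
                           covariates = ftnd_covariates(),
                           seed = NULL) {
  if (!is.numeric(population_size) || length(population_size) != 1L ||
      population_size < 0 || population_size != floor(population_size)) {
    stop("`population_size` must be a non-negative integer", call. = FALSE)
  }
  if (!is.numeric(loadings) || length(loadings) != 6L || any(loadings < 0) ||
      any(!is.finite(loadings))) {
    stop("`loadings` must be 6 non-negative finite numbers", call. = FALSE)
  }
  if (!is.list(thresholds) || length(thresholds) != 6L) {
    stop("`thresholds` must be a list of 6 numeric vectors", call. = FALSE)
  }
  n_cuts <- c(3L, 1L, 1L, 3L, 1L, 1L)
  for (j in 1:6) {
    tj <- thresholds[[j]]
    if (length(tj) != n_cuts[j] || any(!is.finite(tj))) {
      stop("thresholds for item ", j, " must be ", n_cuts[j],
           " finite cut-point(s)", call. = FALSE)
    }
    if (is.unsorted(tj, strictly = TRUE)) {
      stop("thresholds for item ", j, " must be strictly increasing",
           call. = FALSE)
    }
  }
  if (!inherits(covariates, "ftnd_covariates")) {
    covariates <- do.call(ftnd_covariates, covariates)
  }
  structure(list(population_size = as.integer(population_size),
                 loadings = as.numeric(loadings),
                 thresholds = lapply(thresholds, as.numeric),
                 covariates = covariates,
                 seed = if (is.null(seed)) NULL else as.integer(seed)),
            class = "ftnd_generator")
}

#' @export
print.ftnd_generator <- function(x, ...) {
  cat("Synthetic FTND population generator\n")
  cat("  population size:", x$population_size, "\n")
  cat("  item loadings:  ", paste(sprintf("%.3f", x$loadings), collapse = " "),
      "\n")
  cal <- attr(x, "calibration")
  if (!is.null(cal)) {
    cat("  calibrated: yes (", cal$population_size, " subjects, ",
        cal$iterations, " search rounds)\n", sep = "")
  }
  invisible(x)
}

#' Generate a complete synthetic FTND population
#'
#' Draws `n` complete subject records (no missing items) from the latent
#' trait model in `config`.  The output is a data frame with one row per
#' subject and columns `id`, `item1`..`item6`, `gender` (0 = female,
#' 1 = male), `smoke_where` (factor: `no`, `yes_outside`, `yes_inside`) and
#' `smoking_allowed` (0/1).  Identical seeds give bit-identical output.
#'
#' @param config An [ftnd_generator()] configuration.
#' @param n Number of subjects; defaults to `config$population_size`.  `n = 0`
#'   returns an empty dataset.
#' @param seed Integer seed; defaults to `config$seed`.
#' @return A data frame of complete subject records.
#' @export
generate_population <- function(config = ftnd_generator(), n = NULL,
                                seed = NULL) {
  if (!inherits(config, "ftnd_generator")) {
    stop("`config` must be an `ftnd_generator` object", call. = FALSE)
  }
  if (is.null(n)) n <- config$population_size
  if (is.null(seed)) seed <- config$seed
  n <- as.integer(n)
  if (n < 0) stop("`n` must be non-negative", call. = FALSE)
  cov <- config$covariates
  draw <- function() {
    gender <- rbinom(n, 1L, cov$p_male)
    smoke_where <- sample.int(3L, n, replace = TRUE, prob = cov$p_smoke_where)
    trait <- cov$gender_effect * gender +
      cov$smoke_where_effect[smoke_where] + rnorm(n)
    items <- matrix(0L, nrow = n, ncol = 6L,
                    dimnames = list(NULL, ftnd_item_cols()))
    for (j in 1:6) {
      eta <- config$loadings[j] * trait + rnorm(n)
      items[, j] <- findInterval(eta, config$thresholds[[j]])
    }
    p_allowed <- plogis(cov$smoking_allowed_intercept +
                          cov$smoking_allowed_slope * trait)
    smoking_allowed <- as.integer(runif(n) < p_allowed)
    out <- data.frame(id = seq_len(n), items,
                      gender = gender,
                      smoke_where = factor(c("no", "yes_outside",
                                             "yes_inside")[smoke_where],
                                           levels = c("no", "yes_outside",
                                                      "yes_inside")),
                      smoking_allowed = smoking_allowed)
    if (n == 0L) out$smoke_where <- factor(character(0),
                                           levels = levels(out$smoke_where))
    out
  }
  with_seed(seed, draw())
}

#' @rdname generate_population
#' @param object,nsim,... For the [stats::simulate()] method: an
#'   `ftnd_generator`, the number of subjects, and ignored extra arguments.
#' @export
simulate.ftnd_generator <- function(object, nsim = object$population_size,
                                    seed = NULL, ...) {
  generate_population(object, n = nsim, seed = seed)
}

#' Total FTND score of complete records
#'
#' Sums the six item scores per subject (range 0-10); rows with any missing
#' item yield `NA`.
#'
#' @param data A dataset with columns `item1`..`item6`.
#' @return Numeric vector of totals.
#' @export
ftnd_total <- function(data) ftnd_totals(data)

#' Cronbach's alpha of the six FTND items
#'
#' Internal-consistency coefficient `alpha = k/(k-1) * (1 - sum(var_i) /
#' var_total)` with `k = 6` and `n - 1` denominators throughout.
#'
#' @param data A complete dataset (no missing items, at least 2 subjects) or
#'   a numeric matrix of item scores.
#' @return Cronbach's alpha (a real number, at most 1).
#' @export
cronbach_alpha <- function(data) {
  items <- if (is.matrix(data)) data else ftnd_items(data)
  if (nrow(items) < 2L) stop("need at least 2 subjects", call. = FALSE)
  if (anyNA(items)) stop("items must be complete (no missing values)",
                         call. = FALSE)
  k <- ncol(items)
  v_total <- var(rowSums(items))
  if (v_total <= 0) stop("total score variance is zero", call. = FALSE)
  v_items <- sum(apply(items, 2L, var))
  k / (k - 1) * (1 - v_items / v_total)
}

#' Spearman correlation of an item with the rest-total
#'
#' Rank correlation between one item and the sum of the other five items,
#' the item-discrimination summary reported alongside FTND descriptives.
#'
#' @param data A complete dataset (at least 3 subjects).
#' @param item_index Item number, 1 to 6.
#' @return Spearman rank correlation in `[-1, 1]`.
#' @export
spearman_item_rest <- function(data, item_index) {
  items <- if (is.matrix(data)) data else ftnd_items(data)
  if (!item_index %in% seq_len(ncol(items))) {
    stop("`item_index` out of range", call. = FALSE)
  }
  if (nrow(items) < 3L) stop("need at least 3 subjects", call. = FALSE)
  if (anyNA(items)) stop("items must be complete", call. = FALSE)
  x <- items[, item_index]
  rest <- rowSums(items[, -item_index, drop = FALSE])
  if (length(unique(x)) < 2L || length(unique(rest)) < 2L) {
    stop("correlation undefined for a constant column", call. = FALSE)
  }
  cor(x, rest, method = "spearman")
}

# Exact CDF of the latent item variable eta_j = loading * trait + noise.
# The trait mean is a finite mixture over the 6 gender x smoke_where
# combinations, so the CDF is a 6-component normal mixture (smoking_allowed
# is generated downstream of the trait and does not enter).
item_latent_cdf <- function(t, loading, covariates) {
  pg <- c(1 - covariates$p_male, covariates$p_male)
  pw <- covariates$p_smoke_where
  s <- sqrt(loading^2 + 1)
  val <- 0
  for (g in 0:1) {
    for (w in 1:3) {
      mu <- loading * (covariates$gender_effect * g +
                         covariates$smoke_where_effect[w])
      val <- val + pg[g + 1L] * pw[w] * pnorm(t, mean = mu, sd = s)
    }
  }
  val
}

# Solve thresholds on the latent item scale so the item's category
# probabilities equal `probs` exactly (up to root-finding tolerance).
solve_thresholds <- function(probs, loading, covariates) {
  cum <- cumsum(probs)
  cum <- cum[-length(cum)]
  vapply(cum, function(p) {
    uniroot(function(t) item_latent_cdf(t, loading, covariates) - p,
            interval = c(-30, 30), tol = 1e-10)$root
  }, numeric(1))
}
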