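#' Missingness mechanism configuration
#'
#' Bundles the parameters of the two-level item-nonresponse mechanism:
#' a logistic subject-eligibility model (MAR: eligibility driven by gender
#' and the smoke-where covariate; MNAR: by the subject's true total FTND
#' score) followed by independent per-item Bernoulli deletion with
#' probability `p_item` among eligible subjects.
#'
#' Default slopes are the published mechanism coefficients: MAR
#' `beta1 = 0.20` (gender, OR 1.22), `beta2 = -2.12` (smokes outside at
#' home), `beta3 = -1.99` (smokes inside); MNAR `beta1 = 0.2` per FTND
#' point (OR 1.22).  The intercept `beta0` is solved empirically per
#' dataset with [solve_beta0()] so the mean eligibility probability equals
#' `p_sub`.
#'
#' @param mechanism `"MAR"` or `"MNAR"`.
#' @param p_sub Target proportion of subjects eligible for missingness,
#'   in (0, 1).
#' @param p_item Per-item deletion probability among eligible subjects,
#'   in (0, 1].
#' @param beta1,beta2,beta3 Logistic slopes; `beta2`/`beta3` are ignored
#'   under MNAR.
#' @param beta0 Intercept; `NA` until solved for a particular dataset.
#' @param beta0_scope `"dataset"` (re-solve the intercept on each simulated
#'   dataset, the default) or `"population"` (solve once on the source
#'   population and reuse).
#' @return An object of class `ftnd_missingness`.
#' @export
missingness_config <- function(mechanism = c("MAR", "MNAR"),
                               p_sub, p_item,
                               beta1 = 0.20, beta2 = -2.12, beta3 = -1.99,
                               beta0 = NA_real_,
                               beta0_scope = c("dataset", "population")) {
  mechanism <- match.arg(mechanism)
  beta0_scope <- match.arg(beta0_scope)
  if (!is.numeric(p_sub) || length(p_sub) != 1L || p_sub <= 0 || p_sub >= 1) {
    stop("`p_sub` must be in (0, 1)", call. = FALSE)
  }
  if (!is.numeric(p_item) || length(p_item) != 1L || p_item < 0 ||
      p_item > 1) {
    stop("`p_item` must be in [0, 1]", call. = FALSE)
  }
  structure(list(mechanism = mechanism, p_sub = p_sub, p_item = p_item,
                 beta1 = beta1, beta2 = beta2, beta3 = beta3,
                 beta0 = beta0, beta0_scope = beta0_scope),
            class = "ftnd_missingness")
}

# Covariate contribution to the MAR eligibility linear predictor
# (everything except the intercept).
mar_linear_terms <- function(data, beta1, beta2, beta3) {
  if (!all(c("gender", "smoke_where") %in% names(data))) {
    stop("`data` must contain `gender` and `smoke_where`", call. = FALSE)
  }
  if (anyNA(data$gender) || anyNA(data$smoke_where)) {
    stop("covariates must be non-missing for every subject", call. = FALSE)
  }
  sw <- as.integer(data$smoke_where)
  beta1 * data$gender + beta2 * (sw == 2L) + beta3 * (sw == 3L)
}

#' Subject eligibility probabilities under the MAR mechanism
#'
#' Evaluates `plogis(beta0 + beta1*gender + beta2*[smokes outside] +
#' beta3*[smokes inside])` per subject, with "does not smoke at home" as
#' the reference level.
#'
#' @param data Dataset with non-missing `gender` and `smoke_where`.
#' @param beta0 Intercept.
#' @param beta1,beta2,beta3 Slopes (defaults are the published values).
#' @return Probability vector in (0, 1), one per subject.
#' @export
eligibility_probabilities_mar <- function(data, beta0, beta1 = 0.20,
                                          beta2 = -2.12, beta3 = -1.99) {
  plogis(beta0 + mar_linear_terms(data, beta1, beta2, beta3))
}

#' Subject eligibility probabilities under the MNAR mechanism
#'
#' Evaluates `plogis(beta0 + beta1 * total)` on the true (pre-deletion)
#' total FTND scores; with `beta1 > 0` more dependent smokers are more
#' likely to be eligible for missingness.
#'
#' @param true_totals Complete per-subject total scores.
#' @param beta0 Intercept.
#' @param beta1 Slope per FTND point (default 0.2, OR 1.22).
#' @return Probability vector in (0, 1), one per subject.
#' @export
eligibility_probabilities_mnar <- function(true_totals, beta0, beta1 = 0.2) {
  if (anyNA(true_totals)) {
    stop("`true_totals` must be complete (computed before deletion)",
         call. = FALSE)
  }
  plogis(beta0 + beta1 * true_totals)
}

#' Solve the eligibility-model intercept for a target eligibility rate
#'
#' Finds `beta0` such that the mean of `plogis(beta0 + linear_terms)` over
#' subjects equals `p_sub`.  The mean probability is strictly increasing in
#' `beta0`, so the root is unique; it is located by bracketing bisection on
#' `[-50, 50]` and polished until the mean probability is within `tol` of
#' `p_sub`.
#'
#' @param linear_terms Per-subject covariate contributions to the linear
#'   predictor (slopes times covariates, no intercept).
#' @param p_sub Target mean eligibility probability in (0, 1).
#' @param tol Tolerance on the mean probability (default 1e-8).
#' @param max_iter Iteration cap for the bisection (default 200).
#' @return The solved intercept `beta0`.
#' @export
solve_beta0 <- function(linear_terms, p_sub, tol = 1e-8, max_iter = 200L) {
  if (any(!is.finite(linear_terms))) {
    stop("`linear_terms` must be finite", call. = FALSE)
  }
  if (p_sub <= 0 || p_sub >= 1) stop("`p_sub` must be in (0, 1)",
                                     call. = FALSE)
  f <- function(b0) mean(plogis(b0 + linear_terms)) - p_sub
  lo <- -50; hi <- 50
  if (f(lo) > 0 || f(hi) < 0) {
    stop("target eligibility rate not bracketed on [-50, 50]", call. = FALSE)
  }
  for (i in seq_len(max_iter)) {
    mid <- (lo + hi) / 2
    fm <- f(mid)
    if (abs(fm) < tol) return(mid)
    if (fm < 0) lo <- mid else hi <- mid
  }
  stop("intercept solver did not converge within ", max_iter, " iterations",
       call. = FALSE)
}

#' Solve a missingness configuration's intercept on a dataset
#'
#' Convenience wrapper: computes the linear predictor terms implied by the
#' mechanism (covariates for MAR, true totals for MNAR) and fills in
#' `beta0` via [solve_beta0()].
#'
#' @param data Complete dataset.
#' @param config An unsolved [missingness_config()].
#' @return The configuration with `beta0` set.
#' @export
solve_missingness <- function(data, config) {
  terms <- if (config$mechanism == "MAR") {
    mar_linear_terms(data, config$beta1, config$beta2, config$beta3)
  } else {
    config$beta1 * ftnd_totals(data)
  }
  config$beta0 <- solve_beta0(terms, config$p_sub)
  config
}

#' Inject item-level missingness into a complete dataset
#'
#' Draws per-subject eligibility Bernoulli(`plogis(beta0 + terms)`) and,
#' for eligible subjects, deletes each of the six items independently with
#' probability `p_item`.  Covariates are never deleted.  Identical seeds
#' give identical masks.
#'
#' @param data Complete dataset.
#' @param config A [missingness_config()]; if `beta0` is `NA` it is first
#'   solved on `data` (dataset scope).
#' @param seed Optional integer seed.
#' @return A list with `observed` (the dataset with deleted items set to
#'   `NA`) and `mask` (list of `eligible`, a 0/1 vector, and `deleted`, an
#'   n x 6 0/1 matrix; deletions only occur among eligible subjects).
#' @export
draw_missingness <- function(data, config, seed = NULL) {
  if (!inherits(config, "ftnd_missingness")) {
    stop("`config` must come from missingness_config()", call. = FALSE)
  }
  if (is.na(config$beta0)) config <- solve_missingness(data, config)
  probs <- if (config$mechanism == "MAR") {
    eligibility_probabilities_mar(data, config$beta0, config$beta1,
                                  config$beta2, config$beta3)
  } else {
    eligibility_probabilities_mnar(ftnd_totals(data), config$beta0,
                                   config$beta1)
  }
  n <- nrow(data)
  res <- with_seed(seed, {
    eligible <- as.integer(runif(n) < probs)
    deleted <- matrix(as.integer(runif(n * 6L) < config$p_item),
                      nrow = n, ncol = 6L)
    deleted <- deleted * eligible
    list(eligible = eligible, deleted = deleted)
  })
  observed <- data
  items <- ftnd_items(data)
  items[res$deleted == 1L] <- NA_integer_
  observed[, ftnd_item_cols()] <- items
  list(observed = observed,
       mask = list(eligible = res$eligible, deleted = res$deleted),
       config = config)
}
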