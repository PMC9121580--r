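#' @title Scoring methods for FTND datasets with missing items
#' @description Each `score_*` function computes per-subject total FTND
#'   scores from an observed (possibly incomplete) dataset under one rule
#'   for managing missing items, returning an `ftnd_method_result`.
#'   Subjects with no missing items receive the plain row sum under every
#'   method.
#' @name scoring_methods
NULL

new_method_result <- function(method, total, imputed = NULL, n = length(total)) {
  if (is.null(imputed)) {
    imputed <- matrix(NA_real_, nrow = n, ncol = 6L,
                      dimnames = list(NULL, ftnd_item_cols()))
  }
  structure(list(method = method, total = as.numeric(total),
                 imputed = imputed),
            class = "ftnd_method_result")
}

#' @export
print.ftnd_method_result <- function(x, ...) {
  cat("FTND scoring result (method: ", x$method, ")\n", sep = "")
  cat("  subjects:", length(x$total),
      " non-missing totals:", sum(!is.na(x$total)),
      " items imputed:", sum(!is.na(x$imputed)), "\n")
  invisible(x)
}

#' @rdname scoring_methods
#' @param data An observed dataset (columns `item1`..`item6`, possibly
#'   with `NA` items, plus covariates).
#' @return An object of class `ftnd_method_result`: a list with `method`,
#'   `total` (numeric per-subject totals, `NA` where the method declines to
#'   score) and `imputed` (n x 6 matrix of imputed item values, `NA` where
#'   no imputation happened).
#' @details `score_cca()` (complete case analysis) scores only subjects
#'   with all six items observed.
#' @export
score_cca <- function(data) {
  new_method_result("cca", rowSums(ftnd_items(data)))
}

#' @rdname scoring_methods
#' @details `score_drop_one()` scores subjects with at most one missing
#'   item, treating a single missing item as zero; two or more missing
#'   items give a missing total.
#' @export
score_drop_one <- function(data) {
  items <- ftnd_items(data)
  n_miss <- rowSums(is.na(items))
  total <- rowSums(items, na.rm = TRUE)
  total[n_miss > 1L] <- NA_real_
  new_method_result("drop_one", total)
}

#' @rdname scoring_methods
#' @param half_rule If `TRUE`, only subjects with at least half (3) of the
#'   items observed are imputed; others get a missing total.
#' @details `score_item_mean()` replaces each missing item with the mean of
#'   that item's observed values in the current dataset.  Totals may be
#'   non-integer.  An item column with no observed values among subjects
#'   that need it cannot be imputed and is an error.
#' @export
score_item_mean <- function(data, half_rule = FALSE) {
  items <- ftnd_items(data)
  n <- nrow(items)
  n_obs <- rowSums(!is.na(items))
  impute_rows <- if (half_rule) which(n_obs >= 3L & n_obs < 6L)
                 else which(n_obs < 6L)
  col_means <- colMeans(items, na.rm = TRUE)
  imputed <- matrix(NA_real_, n, 6L, dimnames = list(NULL, ftnd_item_cols()))
  filled <- items
  for (j in 1:6) {
    rows <- impute_rows[is.na(items[impute_rows, j])]
    if (length(rows) == 0L) next
    if (!is.finite(col_means[j])) {
      stop("item ", j, " has no observed values; item-mean imputation ",
           "impossible", call. = FALSE)
    }
    filled[rows, j] <- col_means[j]
    imputed[rows, j] <- col_means[j]
  }
  total <- rowSums(filled)
  if (half_rule) total[n_obs < 3L] <- NA_real_
  new_method_result(if (half_rule) "hr_item_mean" else "item_mean",
                    total, imputed)
}

#' @rdname scoring_methods
#' @details `score_proration()` (person-mean imputation) imputes a missing
#'   item from the subject's own answered items, weighted by the item's
#'   maximum score: the imputed value is `max_score * (answered total /
#'   answered possible total)`, where `max_score` is 3 for items 1 and 4
#'   and 1 for the binary items.  The half rule applies: subjects with
#'   fewer than 3 observed items get a missing total.
#' @export
score_proration <- function(data) {
  items <- ftnd_items(data)
  n <- nrow(items)
  ranges <- ftnd_item_ranges()
  n_obs <- rowSums(!is.na(items))
  answered <- rowSums(items, na.rm = TRUE)
  possible <- (!is.na(items)) %*% ranges
  frac <- ifelse(possible > 0, answered / possible, 0)
  imputed <- matrix(NA_real_, n, 6L, dimnames = list(NULL, ftnd_item_cols()))
  total <- answered
  for (j in 1:6) {
    rows <- which(is.na(items[, j]) & n_obs >= 3L)
    if (length(rows) == 0L) next
    imputed[rows, j] <- ranges[j] * frac[rows]
    total[rows] <- total[rows] + imputed[rows, j]
  }
  total[n_obs < 3L] <- NA_real_
  new_method_result("proration", total, imputed)
}

#' Gower's distance between two subject records
#'
#' Mean over the listed variables of per-variable dissimilarities: exact
#' mismatch (0/1) for `gender`, `smoking_allowed` and `smoke_where`;
#' range-normalised absolute difference for item scores (range 3 for items
#' 1 and 4, 1 for the binary items).
#'
#' @param a,b Subject records: single-row data frames (or named lists) with
#'   the listed variables observed.
#' @param variables Character vector of variable names to compare.
#' @return Gower's distance in `[0, 1]`.
#' @export
gower_distance <- function(a, b, variables) {
  ranges <- setNames(ftnd_item_ranges(), ftnd_item_cols())
  d <- vapply(variables, function(v) {
    av <- a[[v]]; bv <- b[[v]]
    if (is.null(av) || is.null(bv) || is.na(av) || is.na(bv)) {
      stop("variable `", v, "` missing on a compared record", call. = FALSE)
    }
    if (v %in% names(ranges)) {
      abs(as.numeric(av) - as.numeric(bv)) / ranges[[v]]
    } else {
      as.numeric(av != bv)
    }
  }, numeric(1))
  mean(d)
}

#' @rdname scoring_methods
#' @param k Donor pool size for the hot deck (default 5).
#' @param seed Optional integer seed for the donor draws.
#' @param strict If `TRUE`, fewer than `k` candidate donors for a recipient
#'   is an error; by default all available candidates are used with a
#'   warning.
#' @details `score_hot_deck()` performs k-nearest-neighbour hot-deck
#'   imputation.  For each recipient (a subject with missing items),
#'   Gower's distance to every candidate donor is computed over `gender`,
#'   `smoking_allowed` and the recipient's observed items; candidates must
#'   observe all of the recipient's missing items as well as every distance
#'   variable.  A single donor is drawn uniformly from the `k` nearest
#'   candidates (distance ties at the k-th rank are all included) and
#'   donates all of the recipient's missing items, so totals stay integer.
#' @export
score_hot_deck <- function(data, k = 5L, seed = NULL, strict = FALSE) {
  items <- ftnd_items(data)
  n <- nrow(items)
  ranges <- ftnd_item_ranges()
  gender <- data$gender
  allowed <- data$smoking_allowed
  if (anyNA(gender) || anyNA(allowed)) {
    stop("hot deck requires non-missing `gender` and `smoking_allowed`",
         call. = FALSE)
  }
  miss <- is.na(items)
  recipients <- which(rowSums(miss) > 0L)
  imputed <- matrix(NA_real_, n, 6L, dimnames = list(NULL, ftnd_item_cols()))
  total <- rowSums(items)
  if (length(recipients) == 0L) {
    return(new_method_result("hot_deck", total, imputed))
  }

  # Recipients sharing a missingness pattern share their candidate set and
  # distance variables; batch the distance computation per pattern.
  pat <- apply(miss[recipients, , drop = FALSE], 1L,
               function(z) paste(which(z), collapse = ","))
  pools <- vector("list", n)
  shortfalls <- 0L
  for (p in unique(pat)) {
    rec <- recipients[pat == p]
    m_set <- as.integer(strsplit(p, ",", fixed = TRUE)[[1]])
    o_set <- setdiff(1:6, m_set)
    cand <- which(rowSums(miss[, c(m_set, o_set), drop = FALSE]) == 0L)
    if (length(cand) == 0L) {
      stop("no candidate donors observe items ",
           paste(m_set, collapse = ","), call. = FALSE)
    }
    n_var <- length(o_set) + 2L
    # distance matrix: recipients in rows, candidates in columns
    d <- outer(gender[rec], gender[cand], "!=") +
      outer(allowed[rec], allowed[cand], "!=")
    for (j in o_set) {
      d <- d + abs(outer(items[rec, j], items[cand, j], "-")) / ranges[j]
    }
    d <- d / n_var
    for (i in seq_along(rec)) {
      di <- d[i, ]
      if (length(cand) < k) {
        if (strict) {
          stop("recipient ", rec[i], ": only ", length(cand),
               " candidate donors (k = ", k, ")", call. = FALSE)
        }
        shortfalls <- shortfalls + 1L
        pools[[rec[i]]] <- cand
      } else {
        kth <- sort(di, partial = k)[k]
        pools[[rec[i]]] <- cand[di <= kth + 1e-9]
      }
    }
  }
  if (shortfalls > 0L) {
    warning(shortfalls, " recipient(s) had fewer than k = ", k,
            " candidate donors; all available donors were used",
            call. = FALSE)
  }

  with_seed(seed, {
    for (r in recipients) {
      pool <- pools[[r]]
      donor <- pool[sample.int(length(pool), 1L)]
      m_set <- which(miss[r, ])
      imputed[r, m_set] <- items[donor, m_set]
      total[r] <- sum(items[r, -m_set]) + sum(items[donor, m_set])
    }
    new_method_result("hot_deck", total, imputed)
  })
}

#' Score a dataset under all six missing-item methods
#'
#' Applies complete case analysis, drop one, item mean, half-rule item
#' mean, proration and the Gower hot deck to the same observed dataset.
#'
#' @inheritParams score_hot_deck
#' @param methods Character subset of
#'   `c("cca", "drop_one", "item_mean", "hr_item_mean", "proration",
#'   "hot_deck")`.
#' @return Named list of `ftnd_method_result` objects.
#' @export
score_all_methods <- function(data, k = 5L, seed = NULL,
                              methods = ftnd_methods()) {
  methods <- match.arg(methods, ftnd_methods(), several.ok = TRUE)
  out <- lapply(methods, function(m) {
    switch(m,
           cca = score_cca(data),
           drop_one = score_drop_one(data),
           item_mean = score_item_mean(data, half_rule = FALSE),
           hr_item_mean = score_item_mean(data, half_rule = TRUE),
           proration = score_proration(data),
           hot_deck = score_hot_deck(data, k = k, seed = seed))
  })
  names(out) <- methods
  out
}

#' The six supported scoring-method labels
#' @return Character vector of method names.
#' @export
ftnd_methods <- function() {
  c("cca", "drop_one", "item_mean", "hr_item_mean", "proration", "hot_deck")
}
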