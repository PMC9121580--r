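#' @export
print.ftnd_sim <- function(x, ...) {
  cat("FTND missing-item simulation study\n")
  cat("  cells:       ", nrow(x$grid$cells), "\n")
  cat("  replications:", x$grid$replications, "per cell\n")
  cat("  methods:     ", paste(x$grid$methods, collapse = ", "), "\n")
  cat("  summary rows:", nrow(x$summary), "\n")
  n_flag <- sum(x$summary$clinically_important, na.rm = TRUE)
  cat("  cells with clinically important mean-FTND bias (>= 1 point):",
      n_flag, "\n")
  invisible(x)
}

# Pivot one measure of the summary into a cells x methods table.
pivot_measure <- function(summary, estimand, column) {
  sub <- summary[summary$estimand == estimand, , drop = FALSE]
  keys <- c("mechanism", "p_sub", "p_item", "n_obs")
  key_of <- function(df) do.call(paste, c(df[keys], sep = "|"))
  cells <- sub[!duplicated(key_of(sub)), keys, drop = FALSE]
  wide <- cells
  for (m in unique(sub$method)) {
    rows <- sub[sub$method == m, , drop = FALSE]
    wide[[m]] <- rows[[column]][match(key_of(cells), key_of(rows))]
  }
  rownames(wide) <- NULL
  wide
}

#' Summarise a simulation study in the four-measure layout
#'
#' Pivots the tidy performance table into four wide tables (methods in
#' columns), one per reported measure: percent bias of the mean FTND,
#' percent bias of the SE of the mean FTND, percent bias of the regression
#' coefficient, and percent bias of its SE.  Also ranks methods per cell
#' by absolute percent bias of the mean FTND and flags clinically
#' important absolute bias (>= 1 point).
#'
#' @param object An `ftnd_sim` from [run_grid()].
#' @param ... Unused.
#' @return An object of class `summary.ftnd_sim`.
#' @export
summary.ftnd_sim <- function(object, ...) {
  s <- object$summary
  measures <- list(
    percent_bias_mean_ftnd =
      pivot_measure(s, "mean_ftnd", "mean_percent_bias"),
    percent_bias_se_mean_ftnd =
      pivot_measure(s, "mean_ftnd", "se_percent_bias"),
    percent_bias_regression_coefficient =
      pivot_measure(s, "regression_coefficient", "mean_percent_bias"),
    percent_bias_se_regression_coefficient =
      pivot_measure(s, "regression_coefficient", "se_percent_bias"))
  mean_rows <- s[s$estimand == "mean_ftnd" & !is.na(s$mean_percent_bias), ]
  ranking <- do.call(rbind, lapply(
    split(mean_rows, interaction(mean_rows[c("mechanism", "p_sub", "p_item",
                                             "n_obs")], drop = TRUE)),
    function(d) {
      d <- d[order(abs(d$mean_percent_bias)), ]
      data.frame(d[1L, c("mechanism", "p_sub", "p_item", "n_obs")],
                 least_biased = d$method[1L],
                 most_biased = d$method[nrow(d)],
                 max_abs_percent_bias = abs(d$mean_percent_bias[nrow(d)]))
    }))
  rownames(ranking) <- NULL
  structure(list(measures = measures, ranking = ranking,
                 clinically_important =
                   s[which(s$clinically_important), , drop = FALSE],
                 replications = object$grid$replications),
            class = "summary.ftnd_sim")
}

#' @export
print.summary.ftnd_sim <- function(x, digits = 2, ...) {
  if (nrow(x$ranking) == 0L) {
    cat("No cells summarised.\n")
    return(invisible(x))
  }
  for (nm in names(x$measures)) {
    cat("\n==", gsub("_", " ", nm), "(%) ==\n")
    tab <- x$measures[[nm]]
    num <- vapply(tab, is.numeric, logical(1)) &
      !names(tab) %in% c("p_sub", "p_item", "n_obs")
    tab[num] <- lapply(tab[num], round, digits = digits)
    print(tab, row.names = FALSE)
  }
  cat("\n== per-cell method ranking by |percent bias| of mean FTND ==\n")
  print(x$ranking, row.names = FALSE)
  if (nrow(x$clinically_important) > 0L) {
    cat("\nCells with clinically important mean-FTND bias (>= 1 point):\n")
    print(x$clinically_important[c("mechanism", "p_sub", "p_item", "n_obs",
                                   "method", "mean_bias")], row.names = FALSE)
  } else {
    cat("\nNo cell reached clinically important mean-FTND bias (1 point).\n")
  }
  invisible(x)
}

#' Plot a performance measure against item-level missingness
#'
#' Draws one panel per mechanism with the chosen measure against `p_item`,
#' one line per scoring method, for a fixed `n_obs` and `p_sub`.
#'
#' @param x An `ftnd_sim`.
#' @param estimand `"mean_ftnd"` or `"regression_coefficient"`.
#' @param measure Summary column to plot (default `"mean_percent_bias"`).
#' @param n_obs,p_sub Cell coordinates to display (defaults: largest
#'   `n_obs`, largest `p_sub` present).
#' @param ... Passed to [graphics::matplot()].
#' @return Invisibly, the plotted wide table.
#' @export
plot.ftnd_sim <- function(x, estimand = "mean_ftnd",
                          measure = "mean_percent_bias",
                          n_obs = max(x$summary$n_obs),
                          p_sub = max(x$summary$p_sub), ...) {
  s <- x$summary[x$summary$estimand == estimand &
                   x$summary$n_obs == n_obs & x$summary$p_sub == p_sub, ]
  if (nrow(s) == 0L) stop("no summary rows for that cell", call. = FALSE)
  mechanisms <- unique(s$mechanism)
  methods <- unique(s$method)
  old <- par(mfrow = c(1, length(mechanisms)))
  on.exit(par(old))
  wide_all <- list()
  for (mech in mechanisms) {
    sub <- s[s$mechanism == mech, ]
    p_items <- sort(unique(sub$p_item))
    mat <- sapply(methods, function(m) {
      rows_m <- sub[sub$method == m, ]
      rows_m[[measure]][match(p_items, rows_m$p_item)]
    })
    matplot(p_items, mat, type = "b", pch = seq_along(methods), lty = 1,
            xlab = "p_item", ylab = paste(measure, "(%)"),
            main = sprintf("%s (n_obs=%d, p_sub=%.1f)", mech, n_obs, p_sub),
            ...)
    legend("bottomleft", legend = methods, col = seq_along(methods),
           pch = seq_along(methods), lty = 1, cex = 0.7, bty = "n")
    wide_all[[mech]] <- mat
  }
  invisible(wide_all)
}
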