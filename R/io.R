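# File interchange: datasets as CSV, configurations as YAML, summaries as
# CSV, manifests as JSON.  The CSV dataset layout is one row per subject,
# columns id,item1..item6,gender,smoke_where,smoking_allowed; missing items
# are empty cells and smoke_where is coded 0 = no, 1 = yes (outside),
# 3 = yes (inside), matching the source questionnaire coding.

smoke_where_codes <- c(no = 0L, yes_outside = 1L, yes_inside = 3L)

#' Write an FTND dataset to CSV
#'
#' @param data Dataset data frame (complete or observed); missing items
#'   become empty cells, `smoke_where` is written as 0/1/3.
#' @param path Output file path.
#' @return Invisibly, `path`.
#' @export
write_ftnd_csv <- function(data, path) {
  out <- data
  out$smoke_where <- smoke_where_codes[as.character(data$smoke_where)]
  write.csv(out, path, row.names = FALSE, na = "", quote = FALSE)
  invisible(path)
}

#' Read an FTND dataset from CSV
#'
#' @param path CSV file in the layout written by [write_ftnd_csv()].
#' @return A dataset data frame with `smoke_where` decoded to its factor
#'   levels and item scores validated against their legal ranges.
#' @export
read_ftnd_csv <- function(path) {
  raw <- read.csv(path, stringsAsFactors = FALSE)
  need <- c("id", ftnd_item_cols(), "gender", "smoke_where",
            "smoking_allowed")
  if (!all(need %in% names(raw))) {
    stop("CSV is missing columns: ",
         paste(setdiff(need, names(raw)), collapse = ", "), call. = FALSE)
  }
  lev <- match(raw$smoke_where, smoke_where_codes)
  if (anyNA(lev)) stop("`smoke_where` must be coded 0, 1 or 3",
                       call. = FALSE)
  raw$smoke_where <- factor(names(smoke_where_codes)[lev],
                            levels = names(smoke_where_codes))
  ranges <- ftnd_item_ranges()
  for (j in 1:6) {
    x <- raw[[ftnd_item_cols()[j]]]
    bad <- !is.na(x) & (x < 0 | x > ranges[j] | x != floor(x))
    if (any(bad)) stop("item ", j, " has scores outside 0..", ranges[j],
                       call. = FALSE)
  }
  raw
}

#' Write a missingness mask to CSV
#'
#' 0/1 debugging export: one row per subject with the eligibility flag and
#' the six deletion flags.
#'
#' @param mask A mask from [draw_missingness()].
#' @param path Output file path.
#' @return Invisibly, `path`.
#' @export
write_mask_csv <- function(mask, path) {
  out <- data.frame(eligible = mask$eligible, mask$deleted)
  names(out) <- c("eligible", paste0("deleted_", ftnd_item_cols()))
  write.csv(out, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Serialise a generator configuration to YAML
#'
#' @param config An [ftnd_generator()].
#' @param path Output file path.
#' @return Invisibly, `path`.
#' @export
write_generator_yaml <- function(config, path) {
  yaml::write_yaml(list(
    population_size = config$population_size,
    loadings = config$loadings,
    thresholds = lapply(config$thresholds, as.numeric),
    covariates = unclass(config$covariates),
    seed = config$seed), path, precision = 15)
  invisible(path)
}

#' Read a generator configuration from YAML
#'
#' @param path YAML file written by [write_generator_yaml()].
#' @return An [ftnd_generator()].
#' @export
read_generator_yaml <- function(path) {
  y <- yaml::read_yaml(path)
  ftnd_generator(population_size = y$population_size,
                 loadings = unlist(y$loadings),
                 thresholds = y$thresholds,
                 covariates = do.call(ftnd_covariates, y$covariates),
                 seed = y$seed)
}

#' Serialise a simulation grid to YAML
#'
#' @param grid An [ftnd_grid()].
#' @param path Output file path.
#' @return Invisibly, `path`.
#' @export
write_grid_yaml <- function(grid, path) {
  yaml::write_yaml(list(
    n_obs = sort(unique(grid$cells$n_obs)),
    mechanisms = unique(grid$cells$mechanism),
    p_sub = sort(unique(grid$cells$p_sub)),
    p_item = sort(unique(grid$cells$p_item)),
    replications = grid$replications,
    methods = grid$methods, k = grid$k, seed = grid$seed,
    ci_type = grid$ci_type), path)
  invisible(path)
}

#' Read a simulation grid from YAML
#'
#' @param path YAML file written by [write_grid_yaml()].
#' @return An [ftnd_grid()].
#' @export
read_grid_yaml <- function(path) {
  y <- yaml::read_yaml(path)
  ftnd_grid(n_obs = unlist(y$n_obs), mechanisms = unlist(y$mechanisms),
            p_sub = unlist(y$p_sub), p_item = unlist(y$p_item),
            replications = y$replications, methods = unlist(y$methods),
            k = y$k, seed = y$seed, ci_type = y$ci_type)
}

#' Export simulation outputs
#'
#' Writes the tidy performance table as `summary.csv` and the run manifest
#' (seeds, configuration, versions) as `manifest.json` in `dir`.
#'
#' @param sim An `ftnd_sim` from [run_grid()].
#' @param dir Output directory (created if absent).
#' @return Invisibly, the paths written.
#' @export
write_sim_outputs <- function(sim, dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  summary_path <- file.path(dir, "summary.csv")
  manifest_path <- file.path(dir, "manifest.json")
  write.csv(sim$summary, summary_path, row.names = FALSE, na = "")
  jsonlite::write_json(sim$manifest, manifest_path, auto_unbox = TRUE,
                       digits = NA, pretty = TRUE)
  invisible(c(summary = summary_path, manifest = manifest_path))
}

#' @export
as.data.frame.ftnd_method_result <- function(x, ...) {
  imputed_items <- apply(x$imputed, 1L, function(row) {
    j <- which(!is.na(row))
    if (length(j) == 0L) return("")
    paste(sprintf("%s=%g", ftnd_item_cols()[j], row[j]), collapse = ";")
  })
  data.frame(id = seq_along(x$total), method = x$method, total = x$total,
             imputed_items = imputed_items, stringsAsFactors = FALSE)
}
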