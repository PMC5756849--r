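#' Write a simulated cohort and its environment to plain-text files
#'
#' Writes `tags.csv` (fish_id, year, rear_type, passage_type, doy,
#' adult_return), `env.csv` (year, doy, river_temp_c, flow_kcfs, sst_c,
#' upwelling, salt_intrusion_km, plume_volume_m3), `pdo.csv` (year, month,
#' pdo) and `truth.json` (generating parameters and realized year random
#' effects) to a directory.
#'
#' @param cohort a `tag_cohort`.
#' @param env the `environment_series` the cohort was generated from.
#' @param dir output directory (created if absent).
#' @return `dir`, invisibly.
#' @export
write_simulation <- function(cohort, env, dir) {
  stopifnot(inherits(cohort, "tag_cohort"), inherits(env, "environment_series"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  utils::write.csv(cohort$tags, file.path(dir, "tags.csv"), row.names = FALSE)
  utils::write.csv(env$daily, file.path(dir, "env.csv"), row.names = FALSE)
  utils::write.csv(env$pdo, file.path(dir, "pdo.csv"), row.names = FALSE)
  truth <- cohort$truth
  jsonlite::write_json(
    list(beta = as.list(truth$beta), sigma = as.list(truth$sigma),
         n_years = truth$n_years, fish_per_year = truth$fish_per_year,
         rear_type = truth$rear_type, passage_type = truth$passage_type,
         doy_window = truth$doy_window,
         random_effects = cohort$ranef),
    file.path(dir, "truth.json"), auto_unbox = TRUE, digits = NA)
  invisible(dir)
}

#' Read tag records from CSV
#' @param path path to a `tags.csv`-schema file.
#' @return data frame of tag records.
#' @export
read_tags <- function(path) {
  utils::read.csv(path, stringsAsFactors = FALSE)
}

#' Read an environmental series from daily and monthly CSV files
#' @param env_csv daily series (`env.csv` schema).
#' @param pdo_csv monthly PDO series (`pdo.csv` schema).
#' @return an `environment_series` object.
#' @export
read_environment <- function(env_csv, pdo_csv) {
  daily <- utils::read.csv(env_csv, stringsAsFactors = FALSE)
  pdo <- utils::read.csv(pdo_csv, stringsAsFactors = FALSE)
  years <- sort(unique(daily$year))
  cool <- years[vapply(years, function(y)
    pdo_binary_index(pdo, y) == 1L, logical(1))]
  structure(list(daily = daily, pdo = pdo, years = years, cool_years = cool),
            class = "environment_series")
}

#' Write a design table with its standardization sidecar
#'
#' @param table a `covariate_table`.
#' @param path CSV output path; a JSON sidecar with the standardization
#'   constants and residual-regression coefficients is written next to it
#'   (same name, `.json` extension).
#' @return `path`, invisibly.
#' @export
write_design <- function(table, path) {
  utils::write.csv(as.data.frame(table), path, row.names = FALSE)
  side <- sub("\\.csv$", ".json", path)
  jsonlite::write_json(
    list(scaling = attr(table, "scaling"),
         residual_fits = attr(table, "residual_fits"),
         quad_from_standardized = attr(table, "quad_from_standardized"),
         window = attr(table, "window")),
    side, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Serialize a fitted model to JSON
#' @param fit a `model_fit`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_fit <- function(fit, path) {
  jsonlite::write_json(
    list(fixed = fit$spec$fixed, random = fit$spec$random,
         grouping = fit$spec$grouping,
         beta_hat = as.list(fit$beta_hat),
         sigma_hat = as.list(fit$sigma_hat),
         cov_beta = fit$cov_beta, loglik = fit$loglik,
         k = fit$k, n = fit$n, aicc = fit$aicc,
         converged = fit$converged, separation = fit$separation,
         conditional_modes = as.data.frame(fit$conditional_modes),
         years = fit$years),
    path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}
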