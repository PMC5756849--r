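#' True generating parameters for a synthetic tag cohort
#'
#' Bundles the parameters of the logistic mixed survival model used to
#' simulate Bernoulli adult-return outcomes: a fixed intercept `beta_0`, fixed
#' slopes on the standardized migration-timing terms (`beta_d`, `beta_d2`) and
#' on the standardized freshwater/marine covariates plus the binary ocean
#' phase index (`beta_t`, `beta_f`, `beta_T`, `beta_U`, `beta_E`, `beta_V`,
#' `beta_I`), and standard deviations `sigma_0`, `sigma_1`, `sigma_2` of the
#' independent year-level random intercept and random slopes on `d` and `d2`.
#'
#' All slopes act on covariates standardized to mean 0 / sd 1 within the
#' generated cohort (the scale on which the model is fitted), except `beta_I`
#' which multiplies the unstandardized 0/1 index.  The default intercept puts
#' baseline survival near 1%, a typical smolt-to-adult return magnitude.
#'
#' @param beta_0 fixed intercept on the logit scale.
#' @param beta_d,beta_d2 fixed slopes for standardized day-of-year and its
#'   quadratic.
#' @param beta_t,beta_f,beta_T,beta_U,beta_E,beta_V fixed slopes for the
#'   standardized river-temperature residual, flow, sea-surface-temperature
#'   residual, upwelling, salt-intrusion residual and plume-volume residual.
#' @param beta_I fixed slope for the binary cool-ocean index (1 = cool phase).
#' @param sigma_0,sigma_1,sigma_2 non-negative standard deviations of the
#'   year random intercept and the year random slopes on `d` and `d2`.
#' @param n_years number of outmigration years (>= 2).
#' @param fish_per_year number of tagged fish per year (>= 1).
#' @param rear_type,passage_type treatment-group labels attached to every
#'   simulated fish.
#' @param doy_window inclusive day-of-year window of passage (default 100-180).
#' @return an object of class `true_parameters`.
#' @export
true_parameters <- function(beta_0 = stats::qlogis(0.01),
                            beta_d = 0, beta_d2 = 0,
                            beta_t = 0, beta_f = 0, beta_T = 0,
                            beta_U = 0, beta_E = 0, beta_V = 0,
                            beta_I = 0,
                            sigma_0 = 0, sigma_1 = 0, sigma_2 = 0,
                            n_years = 15, fish_per_year = 1000,
                            rear_type = c("wild", "hatchery"),
                            passage_type = c("transported", "run_of_river"),
                            doy_window = c(100L, 180L)) {
  rear_type <- match.arg(rear_type)
  passage_type <- match.arg(passage_type)
  if (any(c(sigma_0, sigma_1, sigma_2) < 0))
    stopf("random-effect standard deviations must be non-negative")
  if (n_years < 2) stopf("n_years must be >= 2")
  if (fish_per_year < 1) stopf("fish_per_year must be >= 1")
  if (length(doy_window) != 2 || doy_window[1] > doy_window[2])
    stopf("doy_window must be an increasing pair")
  structure(
    list(beta = c(beta_0 = beta_0, beta_d = beta_d, beta_d2 = beta_d2,
                  beta_t = beta_t, beta_f = beta_f, beta_T = beta_T,
                  beta_U = beta_U, beta_E = beta_E, beta_V = beta_V,
                  beta_I = beta_I),
         sigma = c(sigma_0 = sigma_0, sigma_1 = sigma_1, sigma_2 = sigma_2),
         n_years = as.integer(n_years),
         fish_per_year = as.integer(fish_per_year),
         rear_type = rear_type, passage_type = passage_type,
         doy_window = as.integer(doy_window)),
    class = "true_parameters")
}

#' Generate synthetic daily river/ocean series and a monthly PDO index
#'
#' Emulates the raw environmental inputs of the survival analysis for
#' `n_years` outmigration years: daily (day-of-year 80-190) river temperature,
#' river flow, sea-surface temperature, coastal upwelling index, estuary
#' salt-intrusion length and plume volume, plus a monthly PDO index.
#'
#' The construction guarantees the features the downstream covariate
#' engineering relies on: river temperature trends upward with day of year
#' (so its residualization on timing is non-degenerate), salt intrusion and
#' plume volume are linear in flow plus noise (so their residualization on
#' flow is non-degenerate), and each year's May-September mean PDO is exactly
#' negative in "cool" years and positive in "warm" years.
#'
#' @param n_years number of years to generate.
#' @param cool_year_fraction fraction of years in the cool (negative PDO)
#'   phase; the realized count is `round(cool_year_fraction * n_years)`.
#' @param seed integer RNG seed; output is bit-identical for identical inputs.
#' @param start_year calendar label of the first year.
#' @return an object of class `environment_series`: a list with data frames
#'   `daily` (year, doy, river_temp_c, flow_kcfs, sst_c, upwelling,
#'   salt_intrusion_km, plume_volume_m3) and `pdo` (year, month, pdo), plus
#'   `years` and `cool_years`.
#' @export
generate_environment <- function(n_years, cool_year_fraction = 0.5, seed = 1,
                                 start_year = 1999L) {
  if (!is.numeric(cool_year_fraction) || cool_year_fraction < 0 ||
      cool_year_fraction > 1)
    stopf("cool_year_fraction must lie in [0, 1]")
  if (n_years < 1) stopf("n_years must be >= 1")
  set.seed(as.integer(seed))
  years <- seq.int(start_year, length.out = n_years)
  n_cool <- round(cool_year_fraction * n_years)
  cool_years <- sort(sample(years, n_cool))

  doy <- 80:190
  nd <- length(doy)
  daily <- do.call(rbind, lapply(years, function(yr) {
    temp_off <- stats::rnorm(1, 0, 0.7)
    flow_off <- stats::rnorm(1, 0, 30)
    sst_off <- if (yr %in% cool_years) -0.8 else 0.8
    river_temp <- 8 + 0.09 * (doy - 80) + temp_off + stats::rnorm(nd, 0, 0.8)
    flow <- pmax(30, 150 + 150 * exp(-(doy - 140)^2 / (2 * 20^2)) +
                   flow_off + stats::rnorm(nd, 0, 15))
    sst <- 9.5 + 0.05 * (doy - 80) + sst_off + stats::rnorm(nd, 0, 0.5)
    upwelling <- -40 + 1.2 * (doy - 80) + stats::rnorm(nd, 0, 25)
    salt <- pmax(2, 28 - 0.045 * flow + stats::rnorm(nd, 0, 1.5))
    plume <- pmax(1e8, 4e9 + 1.2e7 * flow + stats::rnorm(nd, 0, 2e8))
    data.frame(year = yr, doy = doy, river_temp_c = river_temp,
               flow_kcfs = flow, sst_c = sst, upwelling = upwelling,
               salt_intrusion_km = salt, plume_volume_m3 = plume)
  }))

  pdo <- do.call(rbind, lapply(years, function(yr) {
    mu <- if (yr %in% cool_years) -1 else 1
    e <- stats::rnorm(12, 0, 0.4)
    ## recenter so the May-September mean is exactly mu (sign is the contract)
    data.frame(year = yr, month = 1:12, pdo = mu + e - mean(e[5:9]))
  }))

  structure(list(daily = daily, pdo = pdo, years = years,
                 cool_years = cool_years),
            class = "environment_series")
}

#' @export
print.environment_series <- function(x, ...) {
  cat("<environment_series> ", length(x$years), " years (",
      min(x$years), "-", max(x$years), "), ",
      length(x$cool_years), " cool\n", sep = "")
  invisible(x)
}

## draw integer day-of-year from a truncated normal on the window
.draw_doy <- function(n, window, mean = 135, sd = 15) {
  lo <- stats::pnorm((window[1] - mean) / sd)
  hi <- stats::pnorm((window[2] - mean) / sd)
  u <- stats::runif(n, lo, hi)
  d <- round(mean + sd * stats::qnorm(u))
  pmin(pmax(d, window[1]), window[2])
}

#' Simulate a tag cohort with Bernoulli adult-return outcomes
#'
#' Draws per-year random effects `b0j, b1j, b2j ~ N(0, sigma^2)` (shared by
#' all fish of that year), a day of passage for each fish from a truncated
#' normal (mean 135, sd 15) on the day-of-year window, builds the covariate
#' design table exactly as [build_design_table()] defines it, forms the linear
#' predictor
#' `logit(p) = beta_0 + b0j + (beta_d + b1j) d + (beta_d2 + b2j) d2 + sum_k beta_k x_k`
#' on the standardized covariate scale, and draws `y ~ Bernoulli(p)`.
#'
#' @param true a [true_parameters()] object.
#' @param env an [generate_environment()] result covering all cohort years.
#' @param seed integer RNG seed.
#' @return an object of class `tag_cohort`: list with `tags` (fish_id, year,
#'   rear_type, passage_type, doy, adult_return), `design` (the covariate
#'   table used, with outcomes filled in), `ranef` (realized per-year random
#'   effects), `p` and `eta` (per-fish survival probability and linear
#'   predictor), and `truth` (the input parameters).
#' @export
generate_cohort <- function(true, env, seed = 1) {
  stopifnot(inherits(true, "true_parameters"),
            inherits(env, "environment_series"))
  years <- env$years[seq_len(true$n_years)]
  if (length(years) < true$n_years)
    stopf("environment covers %d years but %d requested",
          length(env$years), true$n_years)
  .check_env_coverage(env, years, true$doy_window)

  set.seed(as.integer(seed))
  ranef <- data.frame(
    year = years,
    b0 = stats::rnorm(length(years), 0, true$sigma["sigma_0"]),
    b1 = stats::rnorm(length(years), 0, true$sigma["sigma_1"]),
    b2 = stats::rnorm(length(years), 0, true$sigma["sigma_2"]))

  n <- true$n_years * true$fish_per_year
  recs <- data.frame(
    fish_id = sprintf("F%06d", seq_len(n)),
    year = rep(years, each = true$fish_per_year),
    rear_type = true$rear_type,
    passage_type = true$passage_type,
    doy = .draw_doy(n, true$doy_window),
    adult_return = NA_integer_)

  design <- build_design_table(recs, env,
                               lo = true$doy_window[1],
                               hi = true$doy_window[2])
  j <- match(design$year, ranef$year)
  b <- true$beta
  eta <- b["beta_0"] + ranef$b0[j] +
    (b["beta_d"] + ranef$b1[j]) * design$d +
    (b["beta_d2"] + ranef$b2[j]) * design$d2 +
    b["beta_t"] * design$t + b["beta_f"] * design$f +
    b["beta_T"] * design$T + b["beta_U"] * design$U +
    b["beta_E"] * design$E + b["beta_V"] * design$V +
    b["beta_I"] * design$I
  eta <- unname(eta)
  p <- stats::plogis(eta)
  y <- stats::rbinom(n, 1L, p)
  recs$adult_return <- y
  design$y <- y

  structure(list(tags = recs, design = design, ranef = ranef,
                 eta = eta, p = p, truth = true),
            class = "tag_cohort")
}

#' @export
print.tag_cohort <- function(x, ...) {
  cat("<tag_cohort> ", nrow(x$tags), " fish, ", nrow(x$ranef), " years, ",
      "observed survival ", signif(mean(x$tags$adult_return), 3), "\n",
      sep = "")
  invisible(x)
}

.check_env_coverage <- function(env, years, window) {
  need_doy <- (window[1] - 6L):window[2]
  for (yr in years) {
    have <- env$daily$doy[env$daily$year == yr]
    miss <- setdiff(need_doy, have)
    if (length(miss))
      stopf("environment series missing (year=%d, doy=%s)", yr,
            paste(utils::head(miss, 3), collapse = ","))
    mm <- setdiff(5:9, env$pdo$month[env$pdo$year == yr])
    if (length(mm))
      stopf("PDO series missing (year=%d, month=%s)", yr,
            paste(mm, collapse = ","))
  }
  invisible(TRUE)
}
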