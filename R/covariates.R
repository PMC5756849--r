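#' Filter tag records to a day-of-year passage window
#'
#' Retains exactly the records whose day of passage lies in `[lo, hi]`,
#' inclusive on both ends, preserving row order.  The analysis window for
#' spring/summer Chinook passage at Bonneville Dam is days 100-180.
#'
#' @param records data frame with a `doy` column.
#' @param lo,hi inclusive window bounds.
#' @return the filtered data frame.
#' @export
window_filter <- function(records, lo = 100, hi = 180) {
  if (lo > hi) stopf("window bounds out of order: lo=%s > hi=%s", lo, hi)
  records[records$doy >= lo & records$doy <= hi, , drop = FALSE]
}

#' Right-aligned 7-day rolling mean of a daily series
#'
#' Arithmetic mean of the values on days `d-6 ... d`, the convention used for
#' the marine covariates (sea-surface temperature, upwelling, salt intrusion,
#' plume volume) to cover the unobserved estuary/plume transit before ocean
#' entry.
#'
#' @param series data frame with columns `doy` and `value` for a single year.
#' @param d day of year at which the window ends.
#' @return the 7-day mean.
#' @export
rolling_mean_7d <- function(series, d) {
  need <- (d - 6):d
  idx <- match(need, series$doy)
  if (anyNA(idx))
    stopf("rolling mean needs doy %s: missing %s", paste(range(need), collapse = "-"),
          paste(need[is.na(idx)], collapse = ","))
  mean(series$value[idx])
}

## vectorized rolling mean over a full daily table, one value per (year, doy)
## row requested; errors name the first gap
.roll7_lookup <- function(daily, col, year, doy) {
  out <- numeric(length(year))
  for (yr in unique(year)) {
    sub <- daily[daily$year == yr, c("doy", col)]
    sub <- sub[order(sub$doy), ]
    sel <- year == yr
    lo <- min(doy[sel]) - 6L
    hi <- max(doy[sel])
    miss <- setdiff(lo:hi, sub$doy)
    if (length(miss))
      stopf("environment series missing (year=%s, doy=%s)", yr,
            paste(utils::head(miss, 3), collapse = ","))
    roll <- stats::filter(sub[[col]], rep(1 / 7, 7), sides = 1)
    out[sel] <- roll[match(doy[sel], sub$doy)]
  }
  out
}

.daily_lookup <- function(daily, col, year, doy) {
  key <- paste(daily$year, daily$doy)
  idx <- match(paste(year, doy), key)
  if (anyNA(idx)) {
    bad <- which(is.na(idx))[1]
    stopf("environment series missing (year=%s, doy=%s)", year[bad], doy[bad])
  }
  daily[[col]][idx]
}

#' Residuals from a simple linear regression
#'
#' Ordinary least-squares residuals of `response` on `predictor`, used to
#' decorrelate covariates that track each other: river temperature and
#' sea-surface temperature are residualized on day of year, and the estuary
#' salt-intrusion length and plume volume on river flow.
#'
#' @param response,predictor numeric vectors of equal length (>= 3).
#' @return list with `residuals`, `intercept`, `slope`.
#' @export
residualize <- function(response, predictor) {
  if (length(response) != length(predictor))
    stopf("response and predictor lengths differ")
  if (length(response) < 3) stopf("residualize needs >= 3 observations")
  if (stats::sd(predictor) == 0)
    stopf("constant predictor: regression slope undefined")
  fit <- stats::lm.fit(cbind(1, predictor), response)
  list(residuals = unname(fit$residuals),
       intercept = unname(fit$coefficients[1]),
       slope = unname(fit$coefficients[2]))
}

#' Binary PDO phase index for one outmigration year
#'
#' `I = 1` (cool, productive ocean) when the May-September mean of the
#' monthly PDO index is negative; `I = 0` (warm) when it is non-negative.
#'
#' @param pdo_monthly data frame with columns `year`, `month`, `pdo`.
#' @param year the outmigration year.
#' @return integer 0 or 1.
#' @export
pdo_binary_index <- function(pdo_monthly, year) {
  sub <- pdo_monthly[pdo_monthly$year == year & pdo_monthly$month %in% 5:9, ]
  miss <- setdiff(5:9, sub$month)
  if (length(miss))
    stopf("PDO series missing (year=%s, month=%s)", year,
          paste(miss, collapse = ","))
  as.integer(mean(sub$pdo) < 0)
}

.standardize <- function(x) {
  m <- mean(x)
  s <- stats::sd(x)
  ## a numerically degenerate column (e.g. residuals of an exactly linear
  ## relationship) is left centered rather than divided by rounding noise
  if (is.na(s) || s < 1e-8 * max(1, abs(m))) list(z = x - m, mean = m, sd = 1)
  else list(z = (x - m) / s, mean = m, sd = s)
}

#' Build the standardized per-fish covariate design table
#'
#' Applies the full covariate-engineering chain to raw tag records and an
#' environmental series, for one treatment-group dataset:
#'
#' * filter to the day-of-year window (inclusive);
#' * attach river flow `f` and raw river temperature at the (year, day) of
#'   passage, and right-aligned 7-day rolling means of sea-surface
#'   temperature, upwelling index, salt-intrusion length and plume volume;
#' * residualize river temperature on `d` (giving `t`), sea-surface
#'   temperature on `d` (giving `T`), and salt intrusion / plume volume on
#'   flow (giving `E`, `V`), fitted on the fish-level rows of this table;
#' * attach the binary PDO phase index `I` by year;
#' * standardize every covariate except `I` to mean 0 / sd 1; `d2` is the
#'   square of the raw day of year, standardized as its own column (set
#'   `quad_from_standardized = TRUE` to square the standardized `d` instead).
#'
#' Missing environmental days are a hard error naming the gap; nothing is
#' imputed.
#'
#' @param records tag records (fish_id, year, rear_type, passage_type, doy,
#'   adult_return).
#' @param env an `environment_series`.
#' @param lo,hi passage window (default 100-180).
#' @param quad_from_standardized square the standardized `d` rather than the
#'   raw day of year when forming `d2`.
#' @return a `covariate_table`: data frame with identification columns, the
#'   outcome `y`, and standardized covariates `d, d2, t, f, T, U, E, V` plus
#'   the 0/1 `I`; standardization constants and residual-regression
#'   coefficients are stored in attributes `scaling` and `residual_fits`.
#' @export
build_design_table <- function(records, env, lo = 100, hi = 180,
                               quad_from_standardized = FALSE) {
  stopifnot(inherits(env, "environment_series"))
  recs <- window_filter(records, lo, hi)
  if (!nrow(recs)) stopf("no records inside the DOY window [%s, %s]", lo, hi)
  daily <- env$daily
  yr <- recs$year
  d_raw <- recs$doy

  temp_raw <- .daily_lookup(daily, "river_temp_c", yr, d_raw)
  f_raw <- .daily_lookup(daily, "flow_kcfs", yr, d_raw)
  T_raw <- .roll7_lookup(daily, "sst_c", yr, d_raw)
  U_raw <- .roll7_lookup(daily, "upwelling", yr, d_raw)
  E_raw <- .roll7_lookup(daily, "salt_intrusion_km", yr, d_raw)
  V_raw <- .roll7_lookup(daily, "plume_volume_m3", yr, d_raw)

  rt <- residualize(temp_raw, d_raw)
  rT <- residualize(T_raw, d_raw)
  rE <- residualize(E_raw, f_raw)
  rV <- residualize(V_raw, f_raw)

  I_by_year <- vapply(sort(unique(yr)), function(y)
    pdo_binary_index(env$pdo, y), integer(1))
  names(I_by_year) <- sort(unique(yr))
  Ival <- I_by_year[as.character(yr)]

  zd <- .standardize(d_raw)
  d2_raw <- if (quad_from_standardized) zd$z^2 else d_raw^2
  zd2 <- .standardize(d2_raw)
  zt <- .standardize(rt$residuals)
  zf <- .standardize(f_raw)
  zT <- .standardize(rT$residuals)
  zU <- .standardize(U_raw)
  zE <- .standardize(rE$residuals)
  zV <- .standardize(rV$residuals)

  out <- data.frame(
    fish_id = recs$fish_id, year = recs$year,
    rear_type = recs$rear_type, passage_type = recs$passage_type,
    doy = d_raw, y = recs$adult_return,
    d = zd$z, d2 = zd2$z, t = zt$z, f = zf$z,
    T = zT$z, U = zU$z, E = zE$z, V = zV$z,
    I = as.integer(unname(Ival)),
    check.names = FALSE)
  rownames(out) <- NULL

  scaling <- data.frame(
    covariate = c("d", "d2", "t", "f", "T", "U", "E", "V"),
    mean = c(zd$mean, zd2$mean, zt$mean, zf$mean, zT$mean, zU$mean,
             zE$mean, zV$mean),
    sd = c(zd$sd, zd2$sd, zt$sd, zf$sd, zT$sd, zU$sd, zE$sd, zV$sd))
  attr(out, "scaling") <- scaling
  attr(out, "residual_fits") <- list(
    t = rt[c("intercept", "slope")], T = rT[c("intercept", "slope")],
    E = rE[c("intercept", "slope")], V = rV[c("intercept", "slope")])
  attr(out, "quad_from_standardized") <- quad_from_standardized
  attr(out, "window") <- c(lo, hi)
  class(out) <- c("covariate_table", "data.frame")
  out
}
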