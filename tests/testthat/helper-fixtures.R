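## Shared fixture builders.  Everything is generated in code; no stored data.

## deterministic miniature environment: exact linear/known series so that
## covariate-engineering cells can be recomputed by hand in tests
toy_environment <- function(years = 2001:2002, doy = 80:190,
                            sst_fun = function(d) 10 + 0.05 * d + sin(d / 9),
                            pdo_mean = c(-1, 1)) {
  daily <- do.call(rbind, lapply(seq_along(years), function(i) {
    data.frame(year = years[i], doy = doy,
               river_temp_c = 6 + 0.1 * doy + 0.3 * i,
               flow_kcfs = 200 + 50 * sin(doy / 20) + 5 * i,
               sst_c = sst_fun(doy),
               upwelling = -30 + doy,
               salt_intrusion_km = 25 - 0.5 * i - 0.01 * doy,
               plume_volume_m3 = 4e9 + 1e7 * doy)
  }))
  daily$salt_intrusion_km <- 28 - 0.045 * daily$flow_kcfs +
    0.3 * sin(daily$doy / 7)
  daily$plume_volume_m3 <- 4e9 + 1.2e7 * daily$flow_kcfs +
    1e8 * cos(daily$doy / 11)
  pdo <- do.call(rbind, lapply(seq_along(years), function(i)
    data.frame(year = years[i], month = 1:12,
               pdo = pdo_mean[(i - 1) %% length(pdo_mean) + 1])))
  structure(list(daily = daily, pdo = pdo, years = years,
                 cool_years = years[rep_len(pdo_mean, length(years)) < 0]),
            class = "environment_series")
}

toy_records <- function(doys, years = 2001, y = NULL) {
  n <- length(doys)
  data.frame(fish_id = sprintf("F%03d", seq_len(n)),
             year = rep_len(years, n),
             rear_type = "wild", passage_type = "transported",
             doy = doys,
             adult_return = y %||% rep(0L, n))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

## small fitted cohort reused across averaging / D tests (computed once)
small_cohort <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      env <- generate_environment(6, 0.5, seed = 42)
      tp <- true_parameters(beta_0 = qlogis(0.02), beta_d = -0.3,
                            beta_I = 0.8, sigma_0 = 0.25,
                            n_years = 6, fish_per_year = 2000)
      cache <<- list(env = env, cohort = generate_cohort(tp, env, seed = 7))
    }
    cache
  }
})
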