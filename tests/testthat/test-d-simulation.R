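## single-model averaging result wrapped around a hand-built fit
as_avg <- function(fit) {
  structure(list(fits = list(fit), aicc = fit$aicc, delta = 0, weights = 1,
                 in_set = TRUE, level = 0.99), class = "averaging_result")
}

const_fit <- function(p, se = 0) {
  nm <- c("(Intercept)", "d")
  structure(list(spec = model_spec("d", "R0"),
                 beta_hat = stats::setNames(c(stats::qlogis(p), 0), nm),
                 sigma_hat = c(sigma_0 = 0),
                 cov_beta = diag(c(se^2, 0), 2) |> `dimnames<-`(list(nm, nm)),
                 loglik = NA_real_, k = 3, n = 1000, aicc = 100,
                 converged = TRUE, separation = FALSE),
            class = "model_fit")
}

test_that("draw_parameters samples the stated multivariate normal", {
  fit <- const_fit(0.02, se = 0)
  dr <- draw_parameters(fit, 50, seed = 1)
  expect_true(all(dr[, 1] == fit$beta_hat[1]))   # zero covariance: all equal

  fit$cov_beta <- matrix(c(0.04, 0.01, 0.01, 0.09), 2,
                         dimnames = dimnames(fit$cov_beta))
  dr <- draw_parameters(fit, 10000, seed = 2)
  ## CLT bound on the draw mean, per coordinate
  expect_lt(max(abs(colMeans(dr) - fit$beta_hat) /
                  (sqrt(diag(fit$cov_beta)) / 100)), 4)
  expect_equal(cov(dr), fit$cov_beta, tolerance = 0.05)
  expect_identical(draw_parameters(fit, 20, seed = 3),
                   draw_parameters(fit, 20, seed = 3))
})

test_that("scenario_covariates matches a group-mean oracle", {
  fx <- small_cohort()
  tab <- fx$cohort$design
  sc <- scenario_covariates(tab, "cool", day_grid = 100:180)
  expect_equal(sc$I, rep(1L, 81))
  rows <- tab[tab$I == 1, ]
  for (d in intersect(unique(rows$doy), 100:180)) {
    expect_equal(sc$t[sc$doy == d], mean(rows$t[rows$doy == d]),
                 tolerance = 1e-10)
    expect_equal(sc$f[sc$doy == d], mean(rows$f[rows$doy == d]),
                 tolerance = 1e-10)
  }
  ## timing columns come from the stored standardization constants
  scl <- attr(tab, "scaling")
  expect_equal(sc$d, (100:180 - scl$mean[scl$covariate == "d"]) /
                 scl$sd[scl$covariate == "d"], tolerance = 1e-12)
  expect_error(scenario_covariates(tab[tab$I == 1, ], "warm"), "warm")
})

test_that("D identities: identical groups and injected constant survivals", {
  fx <- small_cohort()
  grid <- scenario_covariates(fx$cohort$design, "cool")

  ## identical fits and seeds on both sides -> D = 1 everywhere
  fit <- fit_glmm(model_spec(c("d", "I"), "R0"), fx$cohort$design)
  ds <- simulate_D(as_avg(fit), as_avg(fit), grid, n_draws = 200, seed = 5)
  expect_equal(max(abs(ds$D - 1)), 0)
  expect_true(all(ds$summary$median_D == 1))

  ## injected constant survivals 0.02 / 0.04 -> D = 0.5 at the threshold
  ds2 <- simulate_D(as_avg(const_fit(0.02)), as_avg(const_fit(0.04)),
                    grid, n_draws = 100, seed = 6)
  expect_equal(max(abs(ds2$D - 0.5)), 0, tolerance = 1e-12)
  expect_true(all(!ds2$summary$median_gt_1))
  expect_true(all(ds2$summary$prop_gt_0.5 == 0))
  expect_true(all(ds2$D > 0) && all(ds2$S_transport > 0 &
                                      ds2$S_transport < 1))
})

test_that("D is scale-consistent under matched logit intercept shifts", {
  ## at small p, shifting both intercepts by the same amount moves both
  ## survivals by ~ the same factor and leaves D ~ unchanged
  f_t <- const_fit(0.02)
  f_r <- const_fit(0.03)
  grid <- data.frame(doy = 100:180, d = seq(-1.7, 1.7, length.out = 81))
  d0 <- simulate_D(as_avg(f_t), as_avg(f_r), grid, n_draws = 10, seed = 7)
  f_t2 <- f_t; f_t2$beta_hat[1] <- f_t$beta_hat[1] + log(0.5)
  f_r2 <- f_r; f_r2$beta_hat[1] <- f_r$beta_hat[1] + log(0.5)
  d1 <- simulate_D(as_avg(f_t2), as_avg(f_r2), grid, n_draws = 10, seed = 7)
  expect_lt(max(abs(d1$D / d0$D - 1)), 0.02)
})

test_that("random-effects mode widens the intervals and keeps order invariance", {
  fx <- small_cohort()
  tab <- fx$cohort$design
  grid <- scenario_covariates(tab, "cool")
  fit_t <- fit_glmm(model_spec(c("d", "I"), "R0"), tab)
  tab_r <- tab
  set.seed(30)
  tab_r$y <- rbinom(nrow(tab_r), 1, plogis(qlogis(0.03) - 0.2 * tab_r$d))
  fit_r <- fit_glmm(model_spec(c("d", "I"), "R0"), tab_r)

  fixed <- simulate_D(as_avg(fit_t), as_avg(fit_r), grid,
                      n_draws = 400, seed = 8, include_random = FALSE)
  mixed <- simulate_D(as_avg(fit_t), as_avg(fit_r), grid,
                      n_draws = 400, seed = 8, include_random = TRUE)
  expect_gt(mean(mixed$summary$hi - mixed$summary$lo),
            mean(fixed$summary$hi - fixed$summary$lo))

  ## summaries are invariant to draw order
  perm <- sample(nrow(fixed$D))
  qs <- apply(fixed$D[perm, ], 2, quantile, probs = 0.5, names = FALSE)
  expect_equal(qs, fixed$summary$median_D, tolerance = 1e-12)
})

test_that("a synthetic 1.5x survival ratio is recovered as median D", {
  ## truth: transported survival = 1.5 x run-of-river at every day
  env <- generate_environment(8, 0.5, seed = 50)
  tp_r <- true_parameters(beta_0 = qlogis(0.02), n_years = 8,
                          fish_per_year = 6250,
                          passage_type = "run_of_river")
  tp_t <- true_parameters(beta_0 = qlogis(0.03), n_years = 8,
                          fish_per_year = 6250)
  coh_r <- generate_cohort(tp_r, env, seed = 51)
  coh_t <- generate_cohort(tp_t, env, seed = 52)
  fit_r <- fit_glmm(model_spec("d", "R0"), coh_r$design)
  fit_t <- fit_glmm(model_spec("d", "R0"), coh_t$design)
  grid <- scenario_covariates(coh_t$design, "cool")
  ds <- simulate_D(as_avg(fit_t), as_avg(fit_r), grid,
                   n_draws = 500, seed = 53)
  ## seasonal central value within 5%; every single day within 10%
  expect_lt(abs(median(ds$summary$median_D) - 1.5) / 1.5, 0.05)
  expect_lt(max(abs(ds$summary$median_D - 1.5)) / 1.5, 0.10)
})
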