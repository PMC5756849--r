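test_that("aicc implements the small-sample correction exactly", {
  expect_equal(aicc(-100, 3, 1000), 200 + 6 + 24 / 996)  # 206.0240964
  expect_equal(aicc(-100, 3, 1e9), 206, tolerance = 1e-6) # large-n limit
  expect_equal(aicc(-57.3, 0, 10), 114.6)
  expect_error(aicc(-10, 5, 6), "undefined")
})

test_that("no-random-effect fits match the IRLS logistic oracle", {
  fx <- small_cohort()
  tab <- fx$cohort$design
  for (fixed in list("d", c("d", "d2", "t", "I"))) {
    fit <- fit_glmm(model_spec(fixed, "R0"), tab,
                    sigma_fixed = c(sigma_0 = 0))
    form <- reformulate(sprintf("`%s`", fixed), response = "y")
    oracle <- glm(form, binomial, data = tab,
                  control = glm.control(epsilon = 1e-14, maxit = 50))
    expect_lt(max(abs(fit$beta_hat - coef(oracle))), 1e-6)
    expect_equal(fit$loglik, as.numeric(logLik(oracle)), tolerance = 1e-8)
    ## k excludes the variance component fixed at zero
    expect_equal(fit$k, length(fixed) + 1)
    expect_equal(fit$sigma_hat[["sigma_0"]], 0)
    ## covariance close to the IRLS covariance
    expect_lt(max(abs(fit$cov_beta - vcov(oracle))),
              1e-4 * max(abs(vcov(oracle))))
  }
})

test_that("Laplace log-likelihood agrees with the AGQ-15 oracle", {
  ## battery of seeded small datasets (<= 500 fish, <= 8 years)
  worst <- 0
  for (seed in 1:10) {
    set.seed(seed)
    n_years <- sample(4:8, 1)
    env <- generate_environment(n_years, 0.5, seed = seed)
    tp <- true_parameters(beta_0 = qlogis(0.15), beta_d = -0.3,
                          sigma_0 = 0.5, n_years = n_years,
                          fish_per_year = 500 %/% n_years)
    coh <- generate_cohort(tp, env, seed = seed + 100)
    fit <- fit_glmm(model_spec("d", "R0"), coh$design)
    ll_agq <- loglik_agq(model_spec("d", "R0"), coh$design,
                         fit$beta_hat, fit$sigma_hat)
    worst <- max(worst, abs(fit$loglik - ll_agq))
  }
  expect_lt(worst, 0.1)
})

test_that("AGQ oracle itself is validated by brute-force integration", {
  ## 2-year toy, R0: compare against direct 1-D numerical integration
  fx <- small_cohort()
  tab <- fx$cohort$design
  tab <- tab[tab$year %in% unique(tab$year)[1:2], ]
  spec <- model_spec("d", "R0")
  beta <- c(-3.5, -0.2)
  sigma <- 0.4
  ll_agq <- loglik_agq(spec, tab, beta, sigma, nodes = 25)
  ll_brute <- sum(sapply(unique(tab$year), function(yr) {
    sub <- tab[tab$year == yr, ]
    eta0 <- beta[1] + beta[2] * sub$d
    f <- Vectorize(function(b)
      exp(sum(sub$y * (eta0 + b) - log1p(exp(eta0 + b)))) * dnorm(b, 0, sigma))
    log(integrate(f, -10, 10, rel.tol = 1e-12, abs.tol = 0)$value)
  }))
  expect_equal(ll_agq, ll_brute, tolerance = 1e-6)
})

test_that("fitted estimates and SEs match lme4 glmer on a vector structure", {
  fx <- small_cohort()
  tab <- fx$cohort$design
  fit <- fit_glmm(model_spec(c("d", "I"), "R1"), tab)
  m <- lme4::glmer(y ~ d + I + (1 + d || year), data = tab,
                   family = binomial,
                   control = lme4::glmerControl(calc.derivs = FALSE))
  expect_lt(max(abs(fit$beta_hat - lme4::fixef(m))), 2e-3)
  expect_equal(fit$loglik, as.numeric(logLik(m)), tolerance = 1e-5)
  expect_lt(max(abs(sort(fit$sigma_hat[1:2]) -
                      sort(sqrt(unlist(lme4::VarCorr(m)))))), 2e-3)
})

test_that("sign of a strong timing effect is recovered", {
  env <- generate_environment(8, 0.5, seed = 21)
  tp <- true_parameters(beta_0 = qlogis(0.05), beta_d = 1,
                        n_years = 8, fish_per_year = 6250)  # 50,000 fish
  coh <- generate_cohort(tp, env, seed = 22)
  fit <- fit_glmm(model_spec("d", "R0"), coh$design)
  expect_gt(fit$beta_hat[["d"]], 0)
  expect_lt(abs(fit$beta_hat[["d"]] - 1), 0.15)
})

test_that("reported quantities are invariant to row permutation", {
  fx <- small_cohort()
  tab <- fx$cohort$design
  set.seed(8)
  perm <- sample(nrow(tab))
  tab2 <- tab[perm, ]
  attr(tab2, "scaling") <- attr(tab, "scaling")
  f1 <- fit_glmm(model_spec(c("d", "I"), "R0"), tab)
  f2 <- fit_glmm(model_spec(c("d", "I"), "R0"), tab2)
  expect_equal(f1$loglik, f2$loglik, tolerance = 1e-8)
  expect_equal(f1$beta_hat, f2$beta_hat, tolerance = 1e-6)
  expect_equal(f1$aicc, f2$aicc, tolerance = 1e-8)
})

test_that("fits are equivariant to affine rescaling of a covariate", {
  fx <- small_cohort()
  tab <- fx$cohort$design
  f1 <- fit_glmm(model_spec(c("d", "t"), "R0"), tab)
  tab2 <- tab
  tab2$t <- 3 * tab$t + 1          # un-standardized version of t
  f2 <- fit_glmm(model_spec(c("d", "t"), "R0"), tab2)
  expect_equal(f1$loglik, f2$loglik, tolerance = 1e-6)
  expect_equal(f2$beta_hat[["t"]] * 3, f1$beta_hat[["t"]], tolerance = 1e-4)
  ## identical predictions at matching covariate points
  p1 <- predict_survival(f1, list(d = 0.5, t = 0.2))
  p2 <- predict_survival(f2, list(d = 0.5, t = 3 * 0.2 + 1))
  expect_equal(p1, p2, tolerance = 1e-4)
})

test_that("model_fit invariants hold", {
  fx <- small_cohort()
  fit <- fit_glmm(model_spec(c("d", "d2", "I"), "R2"), fx$cohort$design)
  expect_true(isSymmetric(fit$cov_beta, tol = 1e-12))
  expect_true(all(eigen(fit$cov_beta, symmetric = TRUE,
                        only.values = TRUE)$values >= -1e-12))
  expect_true(all(fit$sigma_hat >= 0))
  expect_equal(fit$k, 4 + 3)
  expect_equal(nrow(fit$conditional_modes), 6)
})

test_that("degenerate inputs are rejected or flagged", {
  fx <- small_cohort()
  tab <- fx$cohort$design
  tab$y <- 0L
  expect_error(fit_glmm(model_spec("d", "R0"), tab), "one outcome class")
  expect_error(fit_glmm(model_spec("d", "R0"), tab[0, ]), "empty")
  expect_error(model_spec(c("t", "f")), "timing index d")
  expect_error(predict_survival(
    fit_glmm(model_spec(c("d", "t"), "R0"), fx$cohort$design),
    list(d = 0)), "t")
})

test_that("predict_survival follows the inverse-logit arithmetic", {
  fx <- small_cohort()
  fit <- fit_glmm(model_spec("d", "R0"), fx$cohort$design)
  fit$beta_hat[] <- c(0, 0)
  expect_equal(predict_survival(fit, list(d = 0)), 0.5)
  fit$beta_hat[] <- c(-4.59512, 0)
  expect_equal(predict_survival(fit, list(d = 0)), 0.01, tolerance = 1e-5)
  ## logit-scale symmetry of random intercept contributions
  fit$beta_hat[] <- c(-2, 0.5)
  hi <- predict_survival(fit, list(d = 1), include_random = TRUE, b = 0.7)
  lo <- predict_survival(fit, list(d = 1), include_random = TRUE, b = -0.7)
  mid <- predict_survival(fit, list(d = 1))
  expect_equal(qlogis(hi) - qlogis(mid), qlogis(mid) - qlogis(lo),
               tolerance = 1e-10)
})

test_that("parameter recovery: truth inside +/- 3 SE at large n", {
  ## scaled-down version of the full recovery study (acceptance suite runs
  ## the 50-replicate battery); here 6 replicates as a unit check
  cover <- 0
  n_rep <- 6
  for (r in seq_len(n_rep)) {
    env <- generate_environment(10, 0.5, seed = 300 + r)
    tp <- true_parameters(beta_0 = qlogis(0.02), beta_d = -0.3,
                          beta_d2 = -0.1, beta_t = 0.15, beta_I = 0.6,
                          sigma_0 = 0.25, n_years = 10,
                          fish_per_year = 5000)
    coh <- generate_cohort(tp, env, seed = 400 + r)
    fit <- fit_glmm(model_spec(c("d", "d2", "t", "I"), "R0"), coh$design)
    se <- sqrt(diag(fit$cov_beta))
    truth <- c(qlogis(0.02), -0.3, -0.1, 0.15, 0.6)
    cover <- cover + all(abs(fit$beta_hat - truth) <= 3 * se)
  }
  expect_gte(cover, n_rep - 1)
})
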