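#' Candidate model structure
#'
#' A candidate model is a subset of fixed-effect covariates (always containing
#' the migration-timing index `d`; `d2` requires `d`) together with one of
#' three year-level random-effect structures:
#' `R0` random intercept only, `R1` random intercept + random slope on `d`,
#' `R2` random intercept + random slopes on `d` and `d2`.  Random effects are
#' independent normals; slopes apply to the same standardized timing columns
#' as the fixed part.
#'
#' @param fixed character vector of covariates from
#'   `d, d2, t, f, T, U, E, V, I`; must contain `d`.
#' @param random one of `"R0"`, `"R1"`, `"R2"`.
#' @return an object of class `model_spec` with elements `fixed` (canonical
#'   order), `random`, and `grouping` (see [classify_grouping()]).
#' @export
model_spec <- function(fixed, random = c("R0", "R1", "R2")) {
  random <- match.arg(random)
  fixed <- canonical_fixed(fixed)
  if (!"d" %in% fixed) stopf("every model must contain the timing index d")
  if ("d2" %in% fixed && !"d" %in% fixed)
    stopf("a quadratic timing term requires the linear term")
  structure(list(fixed = fixed, random = random,
                 grouping = classify_grouping(fixed)),
            class = "model_spec")
}

#' @export
print.model_spec <- function(x, ...) {
  cat("<model_spec> {", paste(x$fixed, collapse = ", "), "} + ", x$random,
      "  [", x$grouping, "]\n", sep = "")
  invisible(x)
}

#' @export
format.model_spec <- function(x, ...) {
  paste0(paste(x$fixed, collapse = "+"), "|", x$random)
}

.random_dim <- function(random) c(R0 = 1L, R1 = 2L, R2 = 3L)[[random]]

#' Fitting control parameters
#'
#' @param maxit maximum outer quasi-Newton iterations.
#' @param grad_tol convergence tolerance on the finite-difference gradient
#'   infinity-norm, relative to `max(1, |loglik|)`.
#' @param inner_tol,inner_maxit tolerance and iteration cap of the inner
#'   Newton solve for the per-year conditional modes.
#' @param sigma_start starting value for random-effect standard deviations.
#' @param boundary_tol standard deviations below this are reported as 0.
#' @param fd_step relative finite-difference step for gradients/Hessians.
#' @return list of control values.
#' @export
glmm_control <- function(maxit = 500, grad_tol = 1e-4,
                         inner_tol = 1e-10, inner_maxit = 50,
                         sigma_start = 0.3, boundary_tol = 1e-6,
                         fd_step = 1e-5) {
  list(maxit = maxit, grad_tol = grad_tol, inner_tol = inner_tol,
       inner_maxit = inner_maxit, sigma_start = sigma_start,
       boundary_tol = boundary_tol, fd_step = fd_step)
}

## --- internal data preparation -------------------------------------------

## Collapse per-fish Bernoulli rows to unique (year, X, Z) rows with
## success/trial counts.  The Bernoulli log-likelihood is unchanged and fits
## scale with the number of unique covariate patterns, not fish.
.glmm_data <- function(spec, table, q) {
  X <- cbind(`(Intercept)` = 1, as.matrix(table[, spec$fixed, drop = FALSE]))
  Zall <- cbind(b0 = rep(1, nrow(table)), b1 = table$d, b2 = table$d2)
  Z <- Zall[, seq_len(q), drop = FALSE]
  yr <- table$year
  y <- table$y
  if (anyNA(y)) stopf("outcome column contains missing values")
  if (length(unique(y)) < 2)
    stopf("only one outcome class present; the model is not identifiable")
  key <- do.call(paste, c(list(yr), asplit(cbind(X, Z), 2)))
  grp <- match(key, unique(key))
  first <- !duplicated(grp)
  s <- as.vector(rowsum(y, grp))
  m <- as.vector(rowsum(rep(1L, length(y)), grp))
  ord <- order(grp[first])
  Xu <- X[first, , drop = FALSE][ord, , drop = FALSE]
  Zu <- Z[first, , drop = FALSE][ord, , drop = FALSE]
  yru <- yr[first][ord]
  years <- sort(unique(yru))
  g <- match(yru, years)
  list(X = Xu, Z = Zu, s = s, m = m, g = g, years = years,
       J = length(years), idx = split(seq_along(g), g),
       n_fish = length(y), p = ncol(X), q = q)
}

## --- Laplace marginal log-likelihood -------------------------------------

## Newton maximization of the joint log-density in b for one year; returns
## mode, value of the joint, and the log-determinant term of the Laplace
## correction, log det(D H) with H the negative joint Hessian at the mode.
## linear solve with escalating ridge; ill-conditioning only arises at
## extreme trial parameters during line searches, where accuracy is moot
.safe_solve <- function(H, g) {
  out <- tryCatch(drop(solve(H, g)), error = function(e) NULL)
  ridge <- max(diag(H)) * 1e-10 + 1e-12
  while (is.null(out) && ridge < max(diag(H))) {
    out <- tryCatch(drop(solve(H + diag(ridge, nrow(H)), g)),
                    error = function(e) NULL)
    ridge <- ridge * 100
  }
  out %||% rep(0, length(g))
}

.year_laplace <- function(eta0, Z, s, m, Dinv, b0, tol, maxit) {
  q <- length(Dinv)
  b <- b0
  joint <- function(b) {
    eta <- eta0 + drop(Z %*% b)
    sum(s * eta - m * log1pexp(eta)) - 0.5 * sum(Dinv * b^2)
  }
  val <- joint(b)
  for (it in seq_len(maxit)) {
    eta <- eta0 + drop(Z %*% b)
    mu <- stats::plogis(eta)
    gr <- drop(crossprod(Z, s - m * mu)) - Dinv * b
    if (max(abs(gr)) < tol) break
    W <- m * mu * (1 - mu)
    H <- crossprod(Z, Z * W) + diag(Dinv, q)
    step <- .safe_solve(H, gr)
    ## step halving
    lam <- 1
    repeat {
      bn <- b + lam * step
      vn <- joint(bn)
      if (vn >= val - 1e-12 || lam < 1e-8) break
      lam <- lam / 2
    }
    if (vn < val + tol && lam < 1e-8) break
    b <- bn
    val <- vn
  }
  eta <- eta0 + drop(Z %*% b)
  mu <- stats::plogis(eta)
  W <- m * mu * (1 - mu)
  H <- crossprod(Z, Z * W) + diag(Dinv, q)
  ## log det(D H) = log det(D Z'WZ + I); D = diag(1/Dinv)
  A <- (1 / Dinv) * H
  ld <- as.numeric(determinant(A, logarithm = TRUE)$modulus)
  list(b = b, val = val, logdet = ld, H = H)
}

## Laplace-approximated marginal log-likelihood at (beta, sigma).
## `state` is an environment carrying warm-start conditional modes.
.laplace_loglik <- function(beta, sigma, dat, ctrl, state = NULL) {
  eta0 <- drop(dat$X %*% beta)
  q <- length(sigma)
  if (q == 0L)
    return(list(loglik = sum(dat$s * eta0 - dat$m * log1pexp(eta0)),
                b = matrix(0, dat$J, 0)))
  Dinv <- 1 / sigma^2
  B <- if (!is.null(state) && !is.null(state$b) && ncol(state$b) == q)
    state$b else matrix(0, dat$J, q)
  ll <- 0
  for (j in seq_len(dat$J)) {
    i <- dat$idx[[j]]
    res <- .year_laplace(eta0[i], dat$Z[i, , drop = FALSE],
                         dat$s[i], dat$m[i], Dinv, B[j, ],
                         ctrl$inner_tol, ctrl$inner_maxit)
    B[j, ] <- res$b
    ll <- ll + res$val - 0.5 * res$logdet
  }
  if (!is.null(state)) state$b <- B
  list(loglik = ll, b = B)
}

.num_grad <- function(fn, x, h_rel) {
  g <- numeric(length(x))
  for (i in seq_along(x)) {
    h <- h_rel * max(1, abs(x[i]))
    xp <- x; xp[i] <- x[i] + h
    xm <- x; xm[i] <- x[i] - h
    g[i] <- (fn(xp) - fn(xm)) / (2 * h)
  }
  g
}

.num_hessian <- function(fn, x, h_rel = 1e-4) {
  p <- length(x)
  H <- matrix(0, p, p)
  f0 <- fn(x)
  h <- h_rel * pmax(1, abs(x))
  for (i in seq_len(p)) {
    xp <- x; xp[i] <- x[i] + h[i]
    xm <- x; xm[i] <- x[i] - h[i]
    H[i, i] <- (fn(xp) + fn(xm) - 2 * f0) / h[i]^2
    if (i < p) for (j in (i + 1):p) {
      xpp <- x; xpp[i] <- x[i] + h[i]; xpp[j] <- x[j] + h[j]
      xpm <- x; xpm[i] <- x[i] + h[i]; xpm[j] <- x[j] - h[j]
      xmp <- x; xmp[i] <- x[i] - h[i]; xmp[j] <- x[j] + h[j]
      xmm <- x; xmm[i] <- x[i] - h[i]; xmm[j] <- x[j] - h[j]
      H[i, j] <- H[j, i] <- (fn(xpp) - fn(xpm) - fn(xmp) + fn(xmm)) /
        (4 * h[i] * h[j])
    }
  }
  H
}

## --- main fit -------------------------------------------------------------

#' Fit the Bernoulli/logit mixed survival model by Laplace-approximated ML
#'
#' Maximizes the marginal likelihood of `y ~ Bernoulli(logit^-1(eta))` with
#' `eta = X beta + Z b_j`, `b_j ~ N(0, diag(sigma^2))` independent across
#' years, replacing each year's integral over its random effects with a
#' Laplace approximation around the conditional mode.  Optimization is
#' quasi-Newton (BFGS) over `(beta, log sigma)` with an inner Newton solve for
#' the conditional modes; the covariance of the fixed effects is the
#' corresponding block of the inverse observed information of the Laplace
#' objective at the optimum.
#'
#' Identical covariate rows are collapsed to binomial counts internally, so
#' cost scales with the number of distinct (year, covariate) patterns rather
#' than the number of fish.
#'
#' @param spec a [model_spec()].
#' @param table a `covariate_table` from [build_design_table()] (or any data
#'   frame with the standardized covariate columns, `year` and `y`).
#' @param sigma_fixed optional named numeric fixing some standard deviations,
#'   e.g. `c(sigma_0 = 0)`; components fixed at 0 are dropped from the
#'   integral (giving, with all components fixed at 0, a plain logistic
#'   regression).
#' @param control a [glmm_control()] list.
#' @return an object of class `model_fit`: estimates `beta_hat` (named),
#'   `sigma_hat`, `cov_beta`, `loglik`, parameter count `k`, number of fish
#'   `n`, `aicc`, `converged` and `separation` flags, and per-year
#'   `conditional_modes`.
#' @export
fit_glmm <- function(spec, table, sigma_fixed = NULL,
                     control = glmm_control()) {
  stopifnot(inherits(spec, "model_spec"))
  if (!nrow(table)) stopf("empty design table")
  q_struct <- .random_dim(spec$random)
  sig_names <- c("sigma_0", "sigma_1", "sigma_2")[seq_len(q_struct)]
  fixed_sig <- rep(NA_real_, q_struct)
  names(fixed_sig) <- sig_names
  if (!is.null(sigma_fixed)) {
    bad <- setdiff(names(sigma_fixed), sig_names)
    if (length(bad))
      stopf("sigma_fixed names not in the random structure: %s",
            paste(bad, collapse = ", "))
    fixed_sig[names(sigma_fixed)] <- sigma_fixed
  }
  active <- which(is.na(fixed_sig) | fixed_sig > 0)   # columns kept in Z
  est_sig <- which(is.na(fixed_sig))                   # optimized components
  dat <- .glmm_data(spec, table, q_struct)
  datA <- dat
  datA$Z <- dat$Z[, active, drop = FALSE]
  datA$q <- length(active)

  p <- dat$p
  ## starting values: weighted logistic regression without random effects
  start_fit <- suppressWarnings(stats::glm.fit(
    dat$X, cbind(dat$s, dat$m - dat$s), family = stats::binomial()))
  beta0 <- start_fit$coefficients
  beta0[!is.finite(beta0)] <- 0

  state <- new.env(parent = emptyenv())
  n_est <- length(est_sig)
  sig_of <- function(ls) {
    s <- fixed_sig[active]
    s[match(est_sig, active)] <- exp(ls)
    unname(s)
  }
  negll <- function(theta) {
    if (any(!is.finite(theta)) || any(abs(theta) > 50)) return(1e10)
    b <- theta[seq_len(p)]
    s <- sig_of(theta[p + seq_len(n_est)])
    v <- -.laplace_loglik(b, s, datA, control, state)$loglik
    if (!is.finite(v)) 1e10 else v
  }
  theta0 <- c(beta0, rep(log(control$sigma_start), n_est))
  opt <- stats::optim(theta0, negll,
                      gr = function(th) .num_grad(negll, th, control$fd_step),
                      method = "BFGS",
                      control = list(maxit = control$maxit, reltol = 1e-13))
  if (opt$convergence != 0) {
    opt2 <- stats::optim(opt$par, negll,
                         gr = function(th) .num_grad(negll, th, control$fd_step),
                         method = "BFGS",
                         control = list(maxit = control$maxit, reltol = 1e-13))
    if (opt2$value <= opt$value) opt <- opt2
  }
  theta <- opt$par
  ## Newton polish of beta when no random effects are being integrated
  if (length(active) == 0L || all(sig_of(theta[p + seq_len(n_est)]) < 1e-8)) {
    beta <- theta[seq_len(p)]
    for (it in 1:25) {
      eta <- drop(dat$X %*% beta)
      mu <- stats::plogis(eta)
      gr <- drop(crossprod(dat$X, dat$s - dat$m * mu))
      W <- dat$m * mu * (1 - mu)
      H <- crossprod(dat$X, dat$X * W)
      step <- tryCatch(solve(H, gr), error = function(e) NULL)
      if (is.null(step) || max(abs(gr)) < 1e-10) break
      beta <- beta + step
    }
    theta[seq_len(p)] <- beta
    opt$value <- negll(theta)
  }

  loglik <- -opt$value
  grad <- .num_grad(negll, theta, control$fd_step)
  converged <- opt$convergence == 0 &&
    max(abs(grad)) < control$grad_tol * max(1, abs(loglik))
  beta_hat <- theta[seq_len(p)]
  names(beta_hat) <- colnames(dat$X)
  sigma_active <- sig_of(theta[p + seq_len(n_est)])
  sigma_hat <- numeric(q_struct)
  sigma_hat[active] <- sigma_active
  sigma_hat[sigma_hat < control$boundary_tol] <- 0
  names(sigma_hat) <- sig_names

  separation <- any(abs(beta_hat) > 15)

  ## observed information over (beta, log sigma); take the beta block.
  ## with no random effects being integrated the information is the exact
  ## logistic X'WX, otherwise a finite-difference Hessian of the objective
  if (length(active) == 0L) {
    eta <- drop(dat$X %*% theta[seq_len(p)])
    mu <- stats::plogis(eta)
    Hth <- crossprod(dat$X, dat$X * (dat$m * mu * (1 - mu)))
  } else {
    Hth <- .num_hessian(negll, theta)
  }
  covth <- tryCatch(solve(Hth), error = function(e) NULL)
  if (is.null(covth)) {
    ev <- eigen((Hth + t(Hth)) / 2, symmetric = TRUE)
    vals <- pmax(ev$values, max(ev$values) * 1e-10)
    covth <- ev$vectors %*% diag(1 / vals, length(vals)) %*% t(ev$vectors)
  }
  cov_beta <- covth[seq_len(p), seq_len(p), drop = FALSE]
  cov_beta <- (cov_beta + t(cov_beta)) / 2
  ev <- eigen(cov_beta, symmetric = TRUE)
  if (any(ev$values < 0))
    cov_beta <- ev$vectors %*% diag(pmax(ev$values, 0), p) %*% t(ev$vectors)
  dimnames(cov_beta) <- list(names(beta_hat), names(beta_hat))

  ## conditional modes at the optimum, expanded to the full structure
  final <- .laplace_loglik(beta_hat, sigma_active, datA, control, state)
  modes <- matrix(0, dat$J, q_struct,
                  dimnames = list(dat$years, c("b0", "b1", "b2")[seq_len(q_struct)]))
  if (length(active)) modes[, active] <- final$b

  k <- p + length(active)   # intercept + slopes + active variance components
  structure(list(spec = spec, beta_hat = beta_hat, sigma_hat = sigma_hat,
                 cov_beta = cov_beta, loglik = loglik, k = k,
                 n = dat$n_fish, aicc = aicc(loglik, k, dat$n_fish),
                 converged = converged, separation = separation,
                 conditional_modes = modes, years = dat$years,
                 grad_norm = max(abs(grad))),
            class = "model_fit")
}

#' @export
print.model_fit <- function(x, ...) {
  cat("<model_fit> ", format(x$spec), "  loglik=", round(x$loglik, 3),
      "  AICc=", round(x$aicc, 3), "  k=", x$k, "  n=", x$n,
      if (!x$converged) "  [NOT CONVERGED]" else "",
      if (x$separation) "  [separation]" else "", "\n", sep = "")
  print(round(x$beta_hat, 4))
  cat("sigma:", paste(signif(x$sigma_hat, 4), collapse = " "), "\n")
  invisible(x)
}

#' Small-sample corrected Akaike information criterion
#'
#' `AICc = -2 loglik + 2k + 2k(k+1)/(n - k - 1)`, with `k` counting the
#' intercept, fixed slopes and one parameter per variance component, and `n`
#' the number of fish.
#'
#' @param loglik maximized log-likelihood.
#' @param k parameter count.
#' @param n sample size; must exceed `k + 1`.
#' @return the AICc value.
#' @export
aicc <- function(loglik, k, n) {
  if (n <= k + 1) stopf("AICc undefined: n=%s <= k+1=%s", n, k + 1)
  -2 * loglik + 2 * k + 2 * k * (k + 1) / (n - k - 1)
}

#' Predict survival probability for one covariate row
#'
#' Inverse-logit of the linear predictor of a fitted model at the supplied
#' (standardized) covariate values; year random effects enter only when
#' `include_random = TRUE` and `b` is supplied.
#'
#' @param fit a `model_fit`.
#' @param newrow named list / one-row data frame supplying every covariate in
#'   the model's fixed set.
#' @param include_random add the random-effect contribution `z' b`.
#' @param b numeric vector of random effects (length = active structure
#'   dimension: intercept, slope on `d`, slope on `d2`).
#' @return survival probability in (0, 1).
#' @export
predict_survival <- function(fit, newrow, include_random = FALSE, b = NULL) {
  stopifnot(inherits(fit, "model_fit"))
  newrow <- as.list(newrow)
  miss <- setdiff(fit$spec$fixed, names(newrow))
  if (length(miss))
    stopf("newrow is missing covariate(s): %s", paste(miss, collapse = ", "))
  eta <- fit$beta_hat[["(Intercept)"]] +
    sum(vapply(fit$spec$fixed, function(v)
      fit$beta_hat[[v]] * as.numeric(newrow[[v]]), numeric(1)))
  if (include_random && !is.null(b)) {
    q <- .random_dim(fit$spec$random)
    if (length(b) != q)
      stopf("b must have length %d for structure %s", q, fit$spec$random)
    z <- c(1, as.numeric(newrow[["d"]] %||% 0),
           as.numeric(newrow[["d2"]] %||% 0))[seq_len(q)]
    eta <- eta + sum(z * b)
  }
  stats::plogis(eta)
}

## vectorized prediction over a covariate grid (rows) for one fit;
## beta may be a replacement coefficient vector (same names/order),
## b an optional random-effect vector applied to every row
.predict_grid <- function(fit, grid, beta = NULL, b = NULL) {
  beta <- beta %||% fit$beta_hat
  X <- cbind(1, as.matrix(grid[, fit$spec$fixed, drop = FALSE]))
  eta <- drop(X %*% beta)
  if (!is.null(b)) {
    q <- .random_dim(fit$spec$random)
    Z <- cbind(1, grid$d, grid$d2)[, seq_len(q), drop = FALSE]
    eta <- eta + drop(Z %*% b[seq_len(q)])
  }
  stats::plogis(eta)
}
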