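#' Gauss-Hermite nodes and weights
#'
#' Nodes and weights for integration against `exp(-x^2)` on the real line,
#' computed by the Golub-Welsch eigenvalue method.  Used by [loglik_agq()] as
#' an independent high-accuracy check on the Laplace approximation.
#'
#' @param n number of nodes.
#' @return list with `nodes` and `weights` (weights sum to `sqrt(pi)`).
#' @export
gauss_hermite <- function(n) {
  if (n == 1) return(list(nodes = 0, weights = sqrt(pi)))
  i <- seq_len(n - 1)
  off <- sqrt(i / 2)
  J <- matrix(0, n, n)
  J[cbind(i, i + 1)] <- off
  J[cbind(i + 1, i)] <- off
  e <- eigen(J, symmetric = TRUE)
  ord <- order(e$values)
  list(nodes = e$values[ord],
       weights = sqrt(pi) * e$vectors[1, ord]^2)
}

#' Marginal log-likelihood by adaptive Gauss-Hermite quadrature
#'
#' Evaluates the exact (to quadrature accuracy) marginal log-likelihood of
#' the Bernoulli/logit mixed model at given parameter values, integrating
#' each year's random effects on a tensor-product Gauss-Hermite grid centered
#' and scaled at the conditional mode.  Serves as an oracle for the Laplace
#' approximation used by [fit_glmm()]; it shares only the model definition,
#' not the fitting path.
#'
#' @param spec a [model_spec()].
#' @param table a `covariate_table`.
#' @param beta named fixed-effect vector (intercept first, then the fixed set
#'   in canonical order).
#' @param sigma standard deviations of the active random effects (length 1-3
#'   for structures R0-R2); components equal to 0 are integrated out trivially.
#' @param nodes quadrature nodes per dimension (default 15).
#' @return the marginal log-likelihood.
#' @export
loglik_agq <- function(spec, table, beta, sigma, nodes = 15) {
  stopifnot(inherits(spec, "model_spec"))
  q_struct <- .random_dim(spec$random)
  if (length(sigma) != q_struct)
    stopf("sigma must have length %d for structure %s", q_struct, spec$random)
  active <- which(sigma > 0)
  dat <- .glmm_data(spec, table, q_struct)
  eta0 <- drop(dat$X %*% beta)
  q <- length(active)
  if (q == 0)
    return(sum(dat$s * eta0 - dat$m * log1pexp(eta0)))
  Z <- dat$Z[, active, drop = FALSE]
  Dinv <- 1 / sigma[active]^2
  gh <- gauss_hermite(nodes)
  U <- as.matrix(expand.grid(rep(list(gh$nodes), q)))
  logw <- rowSums(as.matrix(expand.grid(rep(list(log(gh$weights)), q))))
  ctrl <- glmm_control()
  ll <- 0
  for (j in seq_len(dat$J)) {
    i <- dat$idx[[j]]
    Zj <- Z[i, , drop = FALSE]
    mode <- .year_laplace(eta0[i], Zj, dat$s[i], dat$m[i], Dinv,
                          rep(0, q), ctrl$inner_tol, ctrl$inner_maxit)
    L <- t(chol(solve(mode$H)))            # lower-triangular scale
    ## joint log-density h(b) = loglik_j(b) + log N(b; 0, D)
    h <- function(b) {
      eta <- eta0[i] + drop(Zj %*% b)
      sum(dat$s[i] * eta - dat$m[i] * log1pexp(eta)) -
        0.5 * sum(Dinv * b^2) - 0.5 * q * log(2 * pi) +
        0.5 * sum(log(Dinv))
    }
    hk <- vapply(seq_len(nrow(U)), function(k) {
      b <- mode$b + sqrt(2) * drop(L %*% U[k, ])
      h(b) + sum(U[k, ]^2)
    }, numeric(1))
    ll <- ll + 0.5 * q * log(2) + sum(log(diag(L))) + logsumexp(logw + hk)
  }
  ll
}
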