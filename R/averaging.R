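#' Akaike weights from AICc values
#'
#' `delta_m = AICc_m - min AICc`; `w_m = exp(-delta_m/2) / sum exp(-delta/2)`,
#' computed after the min-shift so the exponentials never overflow.
#' Non-finite AICc values receive weight 0 with a warning.
#'
#' @param aicc_values numeric vector of AICc values.
#' @return list with `delta` and `weight` (weights sum to 1).
#' @export
akaike_weights <- function(aicc_values) {
  if (!length(aicc_values)) stopf("empty AICc vector")
  ok <- is.finite(aicc_values)
  if (!any(ok)) stopf("no finite AICc values")
  if (!all(ok))
    warnf("%d non-finite AICc value(s) assigned weight 0", sum(!ok))
  delta <- aicc_values - min(aicc_values[ok])
  w <- ifelse(ok, exp(-delta / 2), 0)
  list(delta = delta, weight = w / sum(w))
}

#' Membership flags of the 99% confidence set of models
#'
#' Models are sorted by descending weight (ties broken by original index) and
#' accumulated until the running weight sum first reaches the level; the
#' model that crosses the threshold is included.
#'
#' @param weights Akaike weights summing to 1.
#' @param level confidence level (default 0.99).
#' @return logical membership vector in the original order.
#' @export
confidence_set <- function(weights, level = 0.99) {
  ord <- order(-weights, seq_along(weights))
  cum <- cumsum(weights[ord])
  k <- which(cum >= level - 1e-12)[1]
  if (is.na(k)) k <- length(weights)
  member <- logical(length(weights))
  member[ord[seq_len(k)]] <- TRUE
  member
}

#' Conditional model-averaged parameters over the confidence set
#'
#' For each covariate, averages its coefficient over the confidence-set
#' models that contain it, with weights renormalized over those models
#' (the "conditional on the covariate being present" convention).  The
#' relative importance is the summed set-renormalized weight of the models
#' containing the covariate.  The unconditional standard error follows the
#' Burnham-Anderson combination
#' `sqrt( sum w'_m (se_m^2 + (beta_m - avg)^2) )`, and the p-value is a
#' two-sided normal test of `avg / se`.
#'
#' @param fits list of `model_fit` objects.
#' @param weights full-space Akaike weights aligned with `fits`.
#' @param in_set logical confidence-set membership aligned with `fits`.
#' @return data frame with one row per covariate (plus the intercept):
#'   `covariate`, `averaged_beta`, `unconditional_se`, `across_model_sd`,
#'   `relative_importance`, `significance_p`.
#' @export
averaged_parameters <- function(fits, weights, in_set) {
  idx <- which(in_set)
  w_set <- weights[idx] / sum(weights[idx])
  covs <- c("(Intercept)", .covariate_order)
  rows <- lapply(covs, function(v) {
    has <- vapply(fits[idx], function(f) v %in% names(f$beta_hat), logical(1))
    if (!any(has))
      return(data.frame(covariate = v, averaged_beta = NA_real_,
                        unconditional_se = NA_real_,
                        across_model_sd = NA_real_,
                        relative_importance = 0, significance_p = NA_real_))
    wc <- w_set[has] / sum(w_set[has])
    beta <- vapply(fits[idx][has], function(f) f$beta_hat[[v]], numeric(1))
    se <- vapply(fits[idx][has], function(f) sqrt(f$cov_beta[v, v]),
                 numeric(1))
    avg <- sum(wc * beta)
    se_u <- sqrt(sum(wc * (se^2 + (beta - avg)^2)))
    sd_x <- sqrt(sum(wc * (beta - avg)^2))
    data.frame(covariate = v, averaged_beta = avg, unconditional_se = se_u,
               across_model_sd = sd_x,
               relative_importance = sum(w_set[has]),
               significance_p = 2 * stats::pnorm(-abs(avg / se_u)))
  })
  out <- do.call(rbind, rows)
  out[out$relative_importance > 0 | out$covariate == "(Intercept)", ,
      drop = FALSE]
}

#' Model-averaged survival predictions on a covariate grid
#'
#' `Ybar = sum_m w'_m Y_m` on the probability scale over the confidence-set
#' models (optionally restricted to models containing a given covariate),
#' with weights renormalized over the models used.
#'
#' @param fits list of `model_fit` objects.
#' @param weights full-space Akaike weights aligned with `fits`.
#' @param grid data frame of covariate rows (standardized scale).
#' @param in_set logical confidence-set membership; defaults to all models.
#' @param conditional_covariate optional covariate name; only models
#'   containing it contribute.
#' @return numeric vector of averaged survival probabilities, one per row.
#' @export
averaged_predictions <- function(fits, weights, grid, in_set = NULL,
                                 conditional_covariate = NULL) {
  in_set <- in_set %||% rep(TRUE, length(fits))
  use <- in_set
  if (!is.null(conditional_covariate))
    use <- use & vapply(fits, function(f)
      conditional_covariate %in% f$spec$fixed, logical(1))
  if (!any(use)) stopf("no models available for the requested average")
  w <- weights[use] / sum(weights[use])
  P <- vapply(fits[use], function(f) .predict_grid(f, grid),
              numeric(nrow(grid)))
  drop(matrix(P, nrow = nrow(grid)) %*% w)
}

#' Summed weights and set membership by cumulative covariate grouping
#'
#' One row per grouping (MT, MT-FW, MT-FW-M, MT-FW-M-C): number of models in
#' the confidence set and in total, minimum and maximum delta-AICc within the
#' set and over all models, and summed Akaike weight within the set and over
#' all models.  The groupings partition the space, so `weight_all` sums to 1.
#'
#' @param fits list of `model_fit` objects.
#' @param delta,weights delta-AICc and full-space weights aligned with `fits`.
#' @param in_set logical confidence-set membership.
#' @return data frame, one row per grouping present in the space.
#' @export
grouping_weight_table <- function(fits, delta, weights, in_set) {
  grp <- vapply(fits, function(f) f$spec$grouping, "")
  levs <- .grouping_levels[.grouping_levels %in% grp]
  rows <- lapply(levs, function(g) {
    all_i <- grp == g
    set_i <- all_i & in_set
    data.frame(
      grouping = g,
      n_set = sum(set_i), n_all = sum(all_i),
      min_delta_set = if (any(set_i)) min(delta[set_i]) else NA_real_,
      max_delta_set = if (any(set_i)) max(delta[set_i]) else NA_real_,
      min_delta_all = min(delta[all_i]),
      max_delta_all = max(delta[all_i]),
      weight_set = sum(weights[set_i]),
      weight_all = sum(weights[all_i]))
  })
  do.call(rbind, rows)
}

#' Multimodel averaging over a fitted candidate space
#'
#' Computes delta-AICc, Akaike weights, the 99% confidence set, conditional
#' model-averaged coefficients with relative importance, and the per-grouping
#' weight partition, from a list of fitted candidate models.  Fits flagged as
#' non-converged or separated are excluded (with a warning) before weighting.
#'
#' @param fits list of `model_fit` objects.
#' @param level confidence-set level (default 0.99).
#' @return an object of class `averaging_result`: `fits`, `aicc`, `delta`,
#'   `weights`, `in_set`, `coefficients` (see [averaged_parameters()]),
#'   `groupings` (see [grouping_weight_table()]), `n_dropped`.
#' @export
model_average <- function(fits, level = 0.99) {
  ok <- vapply(fits, function(f) isTRUE(f$converged) && !isTRUE(f$separation),
               logical(1))
  if (!any(ok)) stopf("no converged fits to average")
  if (!all(ok))
    warnf("excluding %d non-converged or separation-flagged fit(s)",
          sum(!ok))
  fits <- fits[ok]
  av <- akaike_weights(vapply(fits, `[[`, numeric(1), "aicc"))
  in_set <- confidence_set(av$weight, level)
  structure(list(
    fits = fits,
    aicc = vapply(fits, `[[`, numeric(1), "aicc"),
    delta = av$delta, weights = av$weight, in_set = in_set,
    level = level,
    coefficients = averaged_parameters(fits, av$weight, in_set),
    groupings = grouping_weight_table(fits, av$delta, av$weight, in_set),
    n_dropped = sum(!ok)), class = "averaging_result")
}

#' @export
print.averaging_result <- function(x, ...) {
  cat("<averaging_result> ", length(x$fits), " models, ",
      sum(x$in_set), " in the ", 100 * x$level, "% confidence set\n",
      sep = "")
  print(x$groupings, row.names = FALSE)
  cat("\nModel-averaged coefficients (conditional):\n")
  print(x$coefficients, row.names = FALSE, digits = 4)
  invisible(x)
}
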