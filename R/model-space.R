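#' Cumulative covariate grouping of a candidate model
#'
#' Candidate models are grouped cumulatively along the life cycle: `MT`
#' (migration timing only), `MT-FW` (adds any freshwater covariate `t`, `f`),
#' `MT-FW-M` (adds any marine covariate `T`, `U`, `E`, `V`), `MT-FW-M-C`
#' (adds the climate index `I`).  A model belongs to the highest-level group
#' any of its covariates reaches.
#'
#' @param spec a [model_spec()] or a character vector of fixed covariates.
#' @return one of `"MT"`, `"MT-FW"`, `"MT-FW-M"`, `"MT-FW-M-C"`.
#' @export
classify_grouping <- function(spec) {
  fixed <- if (inherits(spec, "model_spec")) spec$fixed else as.character(spec)
  if (any(fixed %in% .climate_pool)) return("MT-FW-M-C")
  if (any(fixed %in% .marine_pool)) return("MT-FW-M")
  if (any(fixed %in% .freshwater_pool)) return("MT-FW")
  "MT"
}

.subsets <- function(x) {
  if (!length(x)) return(list(character(0)))
  out <- list(character(0))
  for (v in x) out <- c(out, lapply(out, function(s) c(s, v)))
  out
}

.fixed_bitmask <- function(fixed) {
  sum(2^(match(fixed, .covariate_order) - 1))
}

#' Enumerate the constrained all-subsets candidate model space
#'
#' Crosses the timing fixed sets `{d}` and `{d, d2}` (a quadratic term always
#' brings its linear term) with every subset of the freshwater, marine and
#' climate covariate pools and with the three random structures `R0`, `R1`,
#' `R2`.  With the default pools this yields `2 x 4 x 16 x 2 x 3 = 768`
#' candidate models, partitioned into cumulative groupings of sizes
#' 6 / 18 / 360 / 384.  Ordering is canonical (grouping, fixed-set bitmask,
#' random structure), so repeated calls return the identical list.
#'
#' @param freshwater,marine,climate covariate pools; shrink them to build a
#'   reduced space for testing or scaled-down analyses.
#' @param random random structures to cross with every fixed set.
#' @param timing_quadratic include the `{d, d2}` timing branch.
#' @return an object of class `model_space`: list with `specs` (ordered list
#'   of [model_spec()]) and `M` (total count).
#' @export
enumerate_models <- function(freshwater = c("t", "f"),
                             marine = c("T", "U", "E", "V"),
                             climate = "I",
                             random = c("R0", "R1", "R2"),
                             timing_quadratic = TRUE) {
  stopifnot(all(freshwater %in% .freshwater_pool),
            all(marine %in% .marine_pool),
            all(climate %in% .climate_pool))
  timing <- if (timing_quadratic) list("d", c("d", "d2")) else list("d")
  specs <- list()
  for (tm in timing)
    for (fw in .subsets(freshwater))
      for (mar in .subsets(marine))
        for (cl in .subsets(climate))
          for (r in random)
            specs[[length(specs) + 1L]] <-
              model_spec(c(tm, fw, mar, cl), random = r)
  grp <- vapply(specs, function(s) match(s$grouping, .grouping_levels),
                integer(1))
  mask <- vapply(specs, function(s) .fixed_bitmask(s$fixed), numeric(1))
  rnd <- vapply(specs, function(s) match(s$random, c("R0", "R1", "R2")),
                integer(1))
  specs <- specs[order(grp, mask, rnd)]
  structure(list(specs = specs, M = length(specs)), class = "model_space")
}

#' @export
print.model_space <- function(x, ...) {
  tab <- table(factor(vapply(x$specs, `[[`, "", "grouping"),
                      levels = .grouping_levels))
  cat("<model_space> M =", x$M, "candidate models\n")
  print(tab)
  invisible(x)
}

#' @export
as.data.frame.model_space <- function(x, ...) {
  data.frame(
    index = seq_len(x$M),
    fixed = vapply(x$specs, function(s) paste(s$fixed, collapse = "+"), ""),
    random = vapply(x$specs, `[[`, "", "random"),
    grouping = vapply(x$specs, `[[`, "", "grouping"))
}

#' Fit every candidate model in a space
#'
#' @param space a [enumerate_models()] result.
#' @param table a `covariate_table`.
#' @param control a [glmm_control()].
#' @param verbose print one line per fitted model.
#' @return list of `model_fit` objects, in space order.
#' @export
fit_model_space <- function(space, table, control = glmm_control(),
                            verbose = FALSE) {
  stopifnot(inherits(space, "model_space"))
  lapply(seq_len(space$M), function(i) {
    fit <- fit_glmm(space$specs[[i]], table, control = control)
    if (verbose)
      cat(sprintf("[%d/%d] %s AICc=%.2f\n", i, space$M,
                  format(space$specs[[i]]), fit$aicc))
    fit
  })
}
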