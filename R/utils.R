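#' @keywords internal
"_PACKAGE"

## canonical covariate ordering used everywhere a fixed set is stored,
## printed or bit-masked
.covariate_order <- c("d", "d2", "t", "f", "T", "U", "E", "V", "I")

.freshwater_pool <- c("t", "f")
.marine_pool <- c("T", "U", "E", "V")
.climate_pool <- "I"

.grouping_levels <- c("MT", "MT-FW", "MT-FW-M", "MT-FW-M-C")

stopf <- function(...) stop(sprintf(...), call. = FALSE)

warnf <- function(...) warning(sprintf(...), call. = FALSE)

`%||%` <- function(a, b) if (is.null(a)) b else a

## numerically safe log(1 + exp(x))
log1pexp <- function(x) {
  out <- numeric(length(x))
  big <- x > 35
  out[big] <- x[big]
  out[!big] <- log1p(exp(x[!big]))
  out
}

logsumexp <- function(x) {
  m <- max(x)
  if (!is.finite(m)) return(m)
  m + log(sum(exp(x - m)))
}

## order fixed-effect names canonically; error on unknown names
canonical_fixed <- function(fixed) {
  fixed <- unique(as.character(fixed))
  bad <- setdiff(fixed, .covariate_order)
  if (length(bad))
    stopf("unknown covariate(s): %s", paste(bad, collapse = ", "))
  .covariate_order[.covariate_order %in% fixed]
}
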