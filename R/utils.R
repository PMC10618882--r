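#' @keywords internal
"_PACKAGE"

#' @importFrom stats lm logLik pchisq pnorm qnorm qchisq quantile rnorm runif
#'   rbinom sd var cov coef resid fitted anova as.formula complete.cases
#'   mahalanobis model.matrix setNames aggregate predict simulate residuals
#' @importFrom utils read.csv write.csv
NULL

`%||%` <- function(a, b) if (is.null(a)) b else a

## Run code with a temporary RNG state; the caller's .Random.seed is restored.
with_seed <- function(seed, code) {
  if (is.null(seed)) return(force(code))
  has_seed <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_seed) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_seed) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(code)
}

stopf <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)
warnf <- function(fmt, ...) warning(sprintf(fmt, ...), call. = FALSE)

check_prob <- function(x, name) {
  if (!is.numeric(x) || length(x) != 1L || is.na(x) || x < 0 || x > 1)
    stopf("configuration error: '%s' must be a probability in [0, 1]", name)
  x
}

check_nonneg <- function(x, name) {
  if (!is.numeric(x) || length(x) != 1L || is.na(x) || x < 0)
    stopf("configuration error: '%s' must be a non-negative number", name)
  x
}

check_count <- function(x, name, min = 1L) {
  if (!is.numeric(x) || length(x) != 1L || is.na(x) || x < min || x != round(x))
    stopf("configuration error: '%s' must be an integer >= %d", name, min)
  as.integer(x)
}

check_cols <- function(data, cols, where) {
  miss <- setdiff(cols, names(data))
  if (length(miss))
    stopf("%s: missing column(s) %s", where, paste(sQuote(miss), collapse = ", "))
  invisible(data)
}

## Two-sided Wald z p-value and normal-approximation CI for a coefficient.
wald_p <- function(est, se) 2 * pnorm(-abs(est / se))
wald_ci <- function(est, se, level = 0.95) {
  z <- qnorm(1 - (1 - level) / 2)
  c(est - z * se, est + z * se)
}
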