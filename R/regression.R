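#' Z-score variables on the analysis rows
#'
#' Transforms each listed numeric variable to mean 0, SD 1 over the rows of
#' \code{data}. Non-numeric columns (categorical covariates entering models
#' as dummies) must not be listed.
#'
#' @param data data frame.
#' @param variables character vector of columns to standardize.
#' @return \code{data} with the listed columns z-scored.
#' @export
standardize_frame <- function(data, variables) {
  check_cols(data, variables, "standardize_frame")
  for (v in variables) {
    x <- data[[v]]
    if (!is.numeric(x))
      stopf("standardize_frame: '%s' is not numeric", v)
    s <- stats::sd(x, na.rm = TRUE)
    if (!is.finite(s) || s == 0)
      stopf("standardize_frame: '%s' has zero variance on the analysis rows", v)
    data[[v]] <- (x - mean(x, na.rm = TRUE)) / s
  }
  data
}

## Build the covariate part of a model formula.
covariate_terms <- function(covariates) {
  if (inherits(covariates, "covariate_set")) covariates <- covariates$covariates
  covariates %||% character()
}

## Standardize numeric columns among the given, leave categoricals alone.
standardize_numeric <- function(data, vars) {
  num <- vars[vapply(vars, function(v) is.numeric(data[[v]]) &&
                       stats::sd(data[[v]], na.rm = TRUE) > 0, logical(1))]
  if (length(num)) standardize_frame(data, num) else data
}

#' Standardized regression of SR on one resilience factor
#'
#' Fits a linear regression of the (z-scored) outcome on the (z-scored) focal
#' resilience factor plus covariates, on complete cases, and reports the
#' fully standardized focal coefficient with its two-tailed Wald p-value and
#' 95\% CI.
#'
#' @param data analysis rows.
#' @param rf focal predictor column.
#' @param outcome outcome column (SR score).
#' @param covariates a \code{\link{screen_covariates}} result, a character
#'   vector of column names, or \code{NULL}.
#' @param level CI level.
#' @return An object of class \code{"model_result"} (one-row data frame via
#'   \code{as.data.frame}): predictor, \code{beta_std}, \code{se},
#'   \code{ci_lower}, \code{ci_upper}, \code{p}, \code{n}, covariates,
#'   descriptor.
#' @export
fit_rf_model <- function(data, rf, outcome, covariates = NULL, level = 0.95) {
  covs <- covariate_terms(covariates)
  vars <- c(outcome, rf, covs)
  check_cols(data, vars, "fit_rf_model")
  d <- data[stats::complete.cases(data[vars]), vars, drop = FALSE]
  if (nrow(d) <= length(vars) + 1L)
    stopf("fit_rf_model: too few complete cases (n = %d) for %d parameters",
          nrow(d), length(vars))
  d <- standardize_frame(d, c(outcome, rf))
  d <- standardize_numeric(d, covs)
  f <- stats::as.formula(paste(outcome, "~",
                               paste(c(rf, covs), collapse = " + ")))
  fit <- stats::lm(f, d)
  sm <- summary(fit)$coefficients
  row <- which(rownames(sm) == rf)
  if (!length(row)) stopf("fit_rf_model: focal term '%s' dropped from the fit", rf)
  est <- sm[row, "Estimate"]; se <- sm[row, "Std. Error"]
  ci <- est + c(-1, 1) * stats::qt(1 - (1 - level) / 2, fit$df.residual) * se
  structure(list(predictor = rf, beta_std = est, se = se,
                 ci_lower = ci[1], ci_upper = ci[2],
                 p = sm[row, "Pr(>|t|)"], n = nrow(d),
                 covariates = covs,
                 descriptor = sprintf("lm(%s ~ %s + covariates)", outcome, rf),
                 fit = fit),
            class = "model_result")
}

#' @export
print.model_result <- function(x, ...) {
  cat(sprintf("%s: beta_std = %.3f (SE %.3f, 95%% CI %.3f..%.3f), p = %.3g, n = %d\n",
              x$predictor, x$beta_std, x$se, x$ci_lower, x$ci_upper, x$p, x$n))
  invisible(x)
}

#' @export
as.data.frame.model_result <- function(x, ...) {
  data.frame(predictor = x$predictor, beta_std = x$beta_std, se = x$se,
             ci_lower = x$ci_lower, ci_upper = x$ci_upper, p = x$p, n = x$n,
             covariates = paste(x$covariates, collapse = "+"),
             descriptor = x$descriptor, stringsAsFactors = FALSE)
}

## Shared engine for the cross-sectional and prospective per-RF tables.
run_rf_models <- function(data, rfs, outcome, covariates, descriptor) {
  out <- list()
  for (rf in rfs) {
    if (!rf %in% names(data)) {
      warnf("%s: RF column '%s' missing; skipped", descriptor, rf)
      next
    }
    res <- fit_rf_model(data, rf, outcome, covariates)
    out[[rf]] <- as.data.frame(res)
  }
  tab <- do.call(rbind, out)
  rownames(tab) <- NULL
  tab
}

#' Cross-sectional RF-SR associations (one model per baseline RF)
#'
#' Runs a separate standardized multiple regression of baseline SR on each
#' baseline resilience factor plus the covariate set.
#'
#' @param data baseline analysis rows (one per participant, with \code{sr}).
#' @param rfs character vector of RF style/trait columns.
#' @param outcome SR column.
#' @param covariates covariate set (see \code{\link{fit_rf_model}}).
#' @return Data frame with one row per RF, in the order supplied.
#' @export
run_h1 <- function(data, rfs, outcome = "sr", covariates = NULL) {
  run_rf_models(data, rfs, outcome, covariates, "cross-sectional RF models")
}

#' Prospective RF-SR associations (baseline RFs, mean follow-up SR)
#'
#' As \code{\link{run_h1}}, with the per-participant mean follow-up SR
#' (\code{\link{average_sr}}) as the outcome, on the longitudinal sample.
#'
#' @param data one row per longitudinal participant: baseline RFs,
#'   covariates, and the mean follow-up SR.
#' @param rfs,outcome,covariates as in \code{\link{run_h1}}.
#' @return Data frame with one row per RF.
#' @export
run_h2 <- function(data, rfs, outcome = "mean_sr", covariates = NULL) {
  run_rf_models(data, rfs, outcome, covariates, "prospective RF models")
}

#' Baron-Kenny mediation with a distribution-of-the-product CI
#'
#' Estimates the mediation paths by three standardized regressions on
#' complete cases: a (m ~ x + covariates), b and c' (y ~ x + m + covariates),
#' and the total effect c (y ~ x + covariates). The indirect effect is a*b;
#' its CI comes from the distribution of the product of two independent
#' normal path estimates (\code{\link{distribution_of_product_ci}}).
#' Mediation is judged by whether that CI excludes zero.
#'
#' @param data analysis rows.
#' @param x,m,y predictor, mediator, outcome columns.
#' @param covariates covariate set applied to all three regressions.
#' @param level CI level.
#' @param draws,seed Monte Carlo settings for the product CI.
#' @return An object of class \code{"mediation_result"} with paths a, b, c,
#'   c' (estimates and SEs), \code{indirect = a * b}, and its CI.
#' @export
baron_kenny <- function(data, x, m, y, covariates = NULL, level = 0.95,
                        draws = 1e6, seed = NULL) {
  covs <- covariate_terms(covariates)
  vars <- c(x, m, y, covs)
  check_cols(data, vars, "baron_kenny")
  d <- data[stats::complete.cases(data[vars]), vars, drop = FALSE]
  d <- standardize_frame(d, c(x, m, y))
  d <- standardize_numeric(d, covs)
  rhs <- function(terms) paste(c(terms, covs), collapse = " + ")
  cf <- function(fit, term) {
    sm <- summary(fit)$coefficients
    if (qr(fit)$rank < length(coef(fit)))
      stopf("baron_kenny: singular fit (collinear predictors)")
    c(est = sm[term, "Estimate"], se = sm[term, "Std. Error"])
  }
  fa <- stats::lm(stats::as.formula(paste(m, "~", rhs(x))), d)
  fb <- stats::lm(stats::as.formula(paste(y, "~", rhs(c(x, m)))), d)
  fc <- stats::lm(stats::as.formula(paste(y, "~", rhs(x))), d)
  a <- cf(fa, x); b <- cf(fb, m); cp <- cf(fb, x); cc <- cf(fc, x)
  ci <- distribution_of_product_ci(a["est"], a["se"], b["est"], b["se"],
                                   level = level, draws = draws, seed = seed)
  structure(list(x = x, m = m, y = y,
                 a = unname(a["est"]), se_a = unname(a["se"]),
                 b = unname(b["est"]), se_b = unname(b["se"]),
                 c = unname(cc["est"]), se_c = unname(cc["se"]),
                 c_prime = unname(cp["est"]), se_c_prime = unname(cp["se"]),
                 indirect = unname(a["est"] * b["est"]),
                 ci_lower = ci[1], ci_upper = ci[2], level = level,
                 n = nrow(d), method = "distribution_of_product"),
            class = "mediation_result")
}

#' @export
print.mediation_result <- function(x, ...) {
  cat(sprintf("Mediation %s -> %s -> %s (n = %d)\n", x$x, x$m, x$y, x$n))
  cat(sprintf("  a = %.3f (SE %.3f), b = %.3f (SE %.3f)\n",
              x$a, x$se_a, x$b, x$se_b))
  cat(sprintf("  c = %.3f, c' = %.3f\n", x$c, x$c_prime))
  cat(sprintf("  indirect a*b = %.4f, %g%% CI %.4f .. %.4f [%s]\n",
              x$indirect, 100 * x$level, x$ci_lower, x$ci_upper, x$method))
  invisible(x)
}

#' Distribution-of-the-product confidence interval for an indirect effect
#'
#' Computes quantiles of the product Z1 * Z2 of two independent normal
#' variables centered at the path estimates a and b with SDs equal to their
#' standard errors, by seeded Monte Carlo integration with interpolated
#' quantiles. This is the canonical interval for an indirect effect a*b; it
#' is asymmetric around the point estimate, matching the skewed sampling
#' distribution of a product.
#'
#' @param a,se_a,b,se_b path estimates and their standard errors
#'   (\code{se_a, se_b > 0}).
#' @param level CI level in (0, 1).
#' @param draws number of Monte Carlo draws.
#' @param seed optional seed (the caller's RNG state is preserved).
#' @return Numeric length-2 vector \code{c(lower, upper)}.
#' @export
distribution_of_product_ci <- function(a, se_a, b, se_b, level = 0.95,
                                       draws = 1e6, seed = NULL) {
  for (v in list(a = a, se_a = se_a, b = b, se_b = se_b))
    if (!is.numeric(v) || length(v) != 1L || !is.finite(v))
      stopf("distribution_of_product_ci: all inputs must be finite scalars")
  if (se_a <= 0 || se_b <= 0)
    stopf("distribution_of_product_ci: standard errors must be positive")
  if (level <= 0 || level >= 1)
    stopf("distribution_of_product_ci: 'level' must lie in (0, 1)")
  draws <- check_count(draws, "draws")
  with_seed(seed, {
    prod <- (a + se_a * rnorm(draws)) * (b + se_b * rnorm(draws))
    alpha <- (1 - level) / 2
    unname(stats::quantile(prod, c(alpha, 1 - alpha), type = 7))
  })
}
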