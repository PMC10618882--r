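#' Person-mean centering of a time-varying variable
#'
#' Decomposes a panel variable into a stable between-person part (the
#' per-person mean over retained weeks) and a fluctuating within-person part
#' (the deviation from that mean). The two parts are exact:
#' value = person mean + demeaned value, and per-person demeaned values sum
#' to zero.
#'
#' @param data long-format data frame.
#' @param variable column to decompose.
#' @param id participant-id column.
#' @return \code{data} with added columns \code{<variable>_pm} (person mean)
#'   and \code{<variable>_dm} (demeaned).
#' @export
person_center <- function(data, variable, id = "id") {
  check_cols(data, c(variable, id), "person_center")
  pm <- stats::ave(data[[variable]], data[[id]],
                   FUN = function(v) mean(v, na.rm = TRUE))
  data[[paste0(variable, "_pm")]] <- pm
  data[[paste0(variable, "_dm")]] <- data[[variable]] - pm
  data
}

## Core within/between mixed model. Standardizes the outcome and the raw
## time-varying predictor on the analysis rows, decomposes the predictor
## into person mean + demeaned parts, optionally forms lag-1 pairs over
## consecutive assessment indices, and fits
##   z_y ~ demeaned + person_mean + covariates (+ lagged DV) + (1 + demeaned | id)
## with a convergence fallback ladder and Wald-z inference.
fit_wb <- function(data, predictor, outcome, id = "id", t = "t",
                   covariates = NULL, lag = 0L, ar_adjust = FALSE,
                   random_slope = TRUE, level = 0.95) {
  covs <- covariate_terms(covariates)
  vars <- c(predictor, outcome, covs)
  check_cols(data, c(vars, id, t), "within/between model")
  d <- as.data.frame(data)
  d <- d[stats::complete.cases(d[c(vars, id, t)]), , drop = FALSE]
  d <- standardize_frame(d, unique(c(outcome, predictor)))
  d <- standardize_numeric(d, covs)
  d <- person_center(d, predictor, id = id)
  dm <- paste0(predictor, "_dm")
  pm <- paste0(predictor, "_pm")
  if (stats::sd(d[[dm]]) < 1e-10)
    stopf("predictor '%s' has no within-person variance; the within slope is inestimable",
          predictor)

  if (lag > 0L) {
    ## pair (t, t+lag) only over consecutive retained assessment indices
    d <- d[order(d[[id]], d[[t]]), , drop = FALSE]
    nxt <- match(paste(d[[id]], d[[t]] + lag), paste(d[[id]], d[[t]]))
    has_pair <- !is.na(nxt)
    if (!any(has_pair))
      stopf("no participant has %d consecutive retained weeks; lagged model is inestimable",
            lag + 1L)
    pairs <- d[has_pair, , drop = FALSE]
    pairs$.y_next <- d[[outcome]][nxt[has_pair]]
    if (ar_adjust) pairs$.y_now <- pairs[[outcome]]
    d <- pairs
    yvar <- ".y_next"
  } else {
    if (ar_adjust) stopf("ar_adjust requires a lagged model")
    yvar <- outcome
  }

  fixed <- c(dm, pm, covs, if (ar_adjust) ".y_now")
  rhs <- paste(fixed, collapse = " + ")
  forms <- c(
    if (random_slope) sprintf("%s ~ %s + (1 + %s | %s)", yvar, rhs, dm, id),
    if (random_slope) sprintf("%s ~ %s + (1 + %s || %s)", yvar, rhs, dm, id),
    sprintf("%s ~ %s + (1 | %s)", yvar, rhs, id)
  )
  res <- fit_lmer_ladder(forms, d, reml = TRUE)
  if (is.null(res$fit))
    stopf("within/between model for '%s' failed to converge under all random structures",
          predictor)
  fit <- res$fit
  sm <- summary(fit)$coefficients
  grab <- function(term) {
    est <- sm[term, "Estimate"]; se <- sm[term, "Std. Error"]
    list(beta_std = unname(est), se = unname(se),
         ci_lower = wald_ci(est, se, level)[1],
         ci_upper = wald_ci(est, se, level)[2],
         p = wald_p(est, se))
  }
  vc <- as.data.frame(lme4::VarCorr(fit))
  structure(list(
    predictor = predictor, outcome = outcome, lag = lag,
    within = grab(dm), between = grab(pm),
    ar = if (ar_adjust) grab(".y_now") else NULL,
    random_variances = stats::setNames(vc$vcov, paste(vc$grp, vc$var1,
                                                      vc$var2, sep = ".")),
    n_participants = length(unique(d[[id]])), n_obs = nrow(d),
    converged = TRUE, structure = res$formula, notes = res$notes,
    covariates = covs, fit = fit),
    class = "wb_result")
}

#' @export
print.wb_result <- function(x, ...) {
  lbl <- if (x$lag > 0) sprintf("lag-%d", x$lag) else "contemporaneous"
  cat(sprintf("Within/between mixed model (%s): %s -> %s\n",
              lbl, x$predictor, x$outcome))
  fmt <- function(part, name)
    cat(sprintf("  %s: beta_std = %.3f (SE %.3f, CI %.3f..%.3f), p = %.3g\n",
                name, part$beta_std, part$se, part$ci_lower, part$ci_upper,
                part$p))
  fmt(x$within, "within ")
  fmt(x$between, "between")
  if (!is.null(x$ar)) fmt(x$ar, "AR(t)  ")
  cat(sprintf("  n = %d participants, %d observations [%s]\n",
              x$n_participants, x$n_obs, x$structure))
  invisible(x)
}

#' Contemporaneous within-person RF-SR association
#'
#' Mixed model of weekly SR on the same week's demeaned RF mode, with the
#' participant-level RF mean as the between-person term, covariates, a random
#' intercept per participant and a random slope on the demeaned RF.
#' Coefficients are fully standardized (outcome and raw RF z-scored before
#' decomposition, so the within and between parts share a scale).
#'
#' @param data long-format analysis rows (weekly SR, RF modes, covariates).
#' @param rf time-varying RF mode column.
#' @param outcome weekly SR column.
#' @param id,t id and assessment-index columns.
#' @param covariates covariate set or character vector.
#' @param ... passed to the underlying engine (e.g. \code{level}).
#' @return A \code{"wb_result"} with \code{within} and \code{between}
#'   standardized coefficients.
#' @export
fit_contemporaneous <- function(data, rf, outcome = "sr", id = "id", t = "t",
                                covariates = NULL, ...) {
  fit_wb(data, predictor = rf, outcome = outcome, id = id, t = t,
         covariates = covariates, lag = 0L, ...)
}

#' Lagged within-person RF-SR association (RF at t, SR at t+1)
#'
#' As \code{\link{fit_contemporaneous}} with the outcome shifted one
#' assessment ahead; pairs are formed only from consecutive retained weeks.
#' The primary positive-appraisal targets are judged against a
#' Bonferroni-adjusted alpha (alpha / k).
#'
#' @inheritParams fit_contemporaneous
#' @param alpha nominal two-tailed alpha.
#' @param bonferroni_k number of primary hypotheses sharing the alpha.
#' @return A \code{"wb_result"}; \code{alpha_adjusted} and
#'   \code{significant} report the primary-threshold decision for the within
#'   effect.
#' @export
fit_lagged_rf_sr <- function(data, rf, outcome = "sr", id = "id", t = "t",
                             covariates = NULL, alpha = 0.05,
                             bonferroni_k = 1, ...) {
  res <- fit_wb(data, predictor = rf, outcome = outcome, id = id, t = t,
                covariates = covariates, lag = 1L, ...)
  res$alpha_adjusted <- bonferroni_threshold(alpha, bonferroni_k)
  res$significant <- res$within$p < res$alpha_adjusted
  res
}

#' Autoregressive follow-up of a lagged association
#'
#' Re-estimates a lagged model with the outcome's own measurement at time t
#' added as a fixed-effect predictor, so the lagged coefficient no longer
#' absorbs variance shared with the previous measurement. A lagged effect
#' that survives this adjustment is incremental over mere persistence.
#'
#' @inheritParams fit_contemporaneous
#' @return A \code{"wb_result"} with an extra \code{ar} component (the
#'   coefficient of the time-t outcome).
#' @export
fit_autoregressive_followup <- function(data, rf, outcome = "sr", id = "id",
                                        t = "t", covariates = NULL, ...) {
  fit_wb(data, predictor = rf, outcome = outcome, id = id, t = t,
         covariates = covariates, lag = 1L, ar_adjust = TRUE, ...)
}

#' Lagged exposure-RF association (E at t, RF mode at t+1)
#'
#' Tests whether weekly stressor exposure predicts an RF mode one week later
#' (stress-inoculation-style dynamics): demeaned weekly E as the
#' within-person predictor, average weekly E as the between-person term.
#'
#' @inheritParams fit_contemporaneous
#' @param exposure time-varying exposure column.
#' @param rf outcome RF mode column.
#' @param ar_adjust if \code{TRUE}, add the RF at time t as a predictor
#'   (autoregressive follow-up).
#' @return A \code{"wb_result"}.
#' @export
fit_lagged_e_rf <- function(data, rf, exposure = "E", id = "id", t = "t",
                            covariates = NULL, ar_adjust = FALSE, ...) {
  fit_wb(data, predictor = exposure, outcome = rf, id = id, t = t,
         covariates = covariates, lag = 1L, ar_adjust = ar_adjust, ...)
}

#' Intraclass correlation of a panel variable
#'
#' Share of variance attributable to stable between-person differences, from
#' a random-intercept-only mixed model: between variance / (between +
#' residual variance).
#'
#' @param data long-format data frame.
#' @param variable column to assess.
#' @param id participant-id column.
#' @return List with \code{icc} in [0, 1], the two variance components, and
#'   a \code{flag} (\code{"degenerate"} when a component collapses to zero).
#' @export
icc <- function(data, variable, id = "id") {
  check_cols(data, c(variable, id), "icc")
  d <- data[stats::complete.cases(data[[variable]], data[[id]]), , drop = FALSE]
  if (stats::sd(d[[variable]]) == 0)
    return(list(icc = NA_real_, var_between = 0, var_within = 0,
                flag = "degenerate"))
  fit <- suppressWarnings(suppressMessages(lme4::lmer(
    stats::as.formula(sprintf("%s ~ 1 + (1 | %s)", variable, id)), d,
    control = lme4::lmerControl(check.conv.singular = "ignore"))))
  vc <- as.data.frame(lme4::VarCorr(fit))
  vb <- vc$vcov[vc$grp == id]
  vw <- vc$vcov[vc$grp == "Residual"]
  tot <- vb + vw
  flag <- if (vb < 1e-6 * tot || vw < 1e-6 * tot) "degenerate" else "ok"
  list(icc = vb / (vb + vw), var_between = vb, var_within = vw, flag = flag)
}

#' Contemporaneous multilevel mediation via within-person paths
#'
#' Estimates a 1-1-1 mediation among weekly variables with fixed (not
#' random) path slopes: path a from a mixed model of the (standardized)
#' mediator on the demeaned predictor, path b (and c') from a mixed model of
#' the outcome on the demeaned mediator and demeaned predictor, both with
#' person means as between-person terms, covariates, and participant random
#' intercepts. The indirect effect a*b gets a distribution-of-the-product CI.
#'
#' @param data long-format analysis rows.
#' @param x,m,y predictor, mediator, and outcome columns.
#' @param id participant-id column.
#' @param covariates covariate set or character vector.
#' @param level CI level.
#' @param draws,seed Monte Carlo settings for the product CI.
#' @return A \code{"mediation_result"}.
#' @export
multilevel_mediation <- function(data, x, m, y, id = "id", covariates = NULL,
                                 level = 0.95, draws = 1e6, seed = NULL) {
  covs <- covariate_terms(covariates)
  vars <- c(x, m, y, covs)
  check_cols(data, c(vars, id), "multilevel_mediation")
  d <- as.data.frame(data)
  d <- d[stats::complete.cases(d[c(vars, id)]), , drop = FALSE]
  d <- standardize_frame(d, unique(c(x, m, y)))
  d <- standardize_numeric(d, covs)
  d <- person_center(d, x, id = id)
  d <- person_center(d, m, id = id)
  xd <- paste0(x, "_dm"); xp <- paste0(x, "_pm")
  md <- paste0(m, "_dm"); mp <- paste0(m, "_pm")
  fit1 <- function(lhs, terms) {
    f <- sprintf("%s ~ %s + (1 | %s)", lhs,
                 paste(c(terms, covs), collapse = " + "), id)
    suppressMessages(lme4::lmer(stats::as.formula(f), d,
                                control = lme4::lmerControl(
                                  check.conv.singular = "ignore")))
  }
  cf <- function(fit, term) {
    sm <- summary(fit)$coefficients
    c(est = sm[term, "Estimate"], se = sm[term, "Std. Error"])
  }
  fa <- fit1(m, c(xd, xp))
  fb <- fit1(y, c(md, xd, mp, xp))
  fc <- fit1(y, c(xd, xp))
  a <- cf(fa, xd); b <- cf(fb, md); cp <- cf(fb, xd); cc <- cf(fc, xd)
  ci <- distribution_of_product_ci(a["est"], a["se"], b["est"], b["se"],
                                   level = level, draws = draws, seed = seed)
  structure(list(x = x, m = m, y = y,
                 a = unname(a["est"]), se_a = unname(a["se"]),
                 b = unname(b["est"]), se_b = unname(b["se"]),
                 c = unname(cc["est"]), se_c = unname(cc["se"]),
                 c_prime = unname(cp["est"]), se_c_prime = unname(cp["se"]),
                 indirect = unname(a["est"] * b["est"]),
                 ci_lower = ci[1], ci_upper = ci[2], level = level,
                 n = nrow(d),
                 method = "multilevel fixed-slope, distribution_of_product"),
            class = "mediation_result")
}
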