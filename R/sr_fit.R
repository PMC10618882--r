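#' Mahalanobis outlier gate for the exposure-symptom distribution
#'
#' Flags (E, P) pairs whose squared Mahalanobis distance from the sample
#' centroid exceeds the chi-square quantile with 2 degrees of freedom at the
#' given upper-tail probability (default .001, cutoff 13.8155). Flagged cases
#' are excluded from normative-line fitting and receive no SR score.
#'
#' @param E,P numeric vectors of exposure and symptom scores (equal length).
#' @param p upper-tail probability defining the exclusion cutoff.
#' @return List with \code{retain} (logical), \code{d2} (squared distances),
#'   \code{cutoff}, and \code{n_excluded}.
#' @export
mahalanobis_outliers <- function(E, P, p = 0.001) {
  if (length(E) != length(P)) stopf("E and P must have equal length")
  ok <- stats::complete.cases(E, P)
  if (sum(ok) < 3L) stopf("need at least 3 complete (E, P) pairs")
  X <- cbind(E, P)
  S <- stats::cov(X[ok, , drop = FALSE])
  if (!is.finite(determinant(S)$modulus) || det(S) <= .Machine$double.eps)
    stopf(paste("singular (E, P) covariance: the distances are undefined;",
                "jitter the data or gate manually"))
  d2 <- rep(NA_real_, length(E))
  d2[ok] <- stats::mahalanobis(X[ok, , drop = FALSE],
                               colMeans(X[ok, , drop = FALSE]), S)
  cutoff <- qchisq(1 - p, df = 2)
  retain <- !is.na(d2) & d2 <= cutoff
  list(retain = retain, d2 = d2, cutoff = cutoff,
       n_excluded = sum(!retain & ok))
}

#' Fit the normative exposure-symptom line and stressor-reactivity scores
#'
#' The stressor-reactivity (SR) score of an observation is the residual of
#' its symptom score P on the sample's normative E-P regression line: lower
#' SR means fewer symptoms than expected for the experienced exposure, i.e.
#' higher outcome-based resilience. The line is fitted by ordinary least
#' squares for a cross-sectional sample (\code{method = "ols"}, typically one
#' baseline row per participant) or, for repeated weekly data, by a linear
#' mixed model with correlated participant-level random intercepts and
#' exposure slopes (\code{method = "mixed"}), whose \emph{fixed} effects
#' define the line. Multivariate outliers in the pooled (E, P) distribution
#' are gated out beforehand via \code{\link{mahalanobis_outliers}}; gated
#' rows get \code{NA} SR scores.
#'
#' If the full random structure fails to converge, the model falls back in
#' steps (uncorrelated random effects, then random intercept only, then OLS),
#' each step reported via a warning and recorded in the result.
#'
#' @param formula model formula naming the symptom and exposure columns,
#'   e.g. \code{P ~ E}.
#' @param data data frame with the model variables (and \code{id} for the
#'   mixed method).
#' @param id name of the participant-id column (mixed method).
#' @param method \code{"ols"} or \code{"mixed"}.
#' @param outlier_p upper-tail probability of the Mahalanobis gate;
#'   \code{NULL} disables gating.
#' @param reml use REML for the mixed fit (default); likelihood-ratio
#'   comparisons refit by ML.
#' @return An object of class \code{"sr_fit"}: the normative line
#'   (\code{line}), the gated data with an \code{sr} column (\code{data}),
#'   the underlying model fit (\code{fit}), and gate/fallback metadata.
#'   Methods: \code{print}, \code{summary}, \code{coef}, \code{predict},
#'   \code{residuals}, \code{fitted}, \code{plot}.
#' @examples
#' d <- data.frame(E = c(0, 10, 20, 30, 40), P = c(2, 3, 4, 5, 6))
#' fit <- sr_fit(P ~ E, d, method = "ols", outlier_p = NULL)
#' coef(fit)        # intercept 2, slope 0.1
#' residuals(fit)   # all zero: every point lies on the line
#' @export
sr_fit <- function(formula = P ~ E, data, id = "id",
                   method = c("ols", "mixed"), outlier_p = 0.001,
                   reml = TRUE) {
  method <- match.arg(method)
  vars <- all.vars(formula)
  if (length(vars) != 2L)
    stopf("'formula' must have the form symptoms ~ exposure")
  pvar <- vars[1L]; evar <- vars[2L]
  check_cols(data, c(pvar, evar), "sr_fit")
  if (method == "mixed") check_cols(data, id, "sr_fit (mixed)")
  data <- as.data.frame(data)

  complete <- stats::complete.cases(data[[pvar]], data[[evar]])
  if (!is.null(outlier_p)) {
    gate <- mahalanobis_outliers(data[[evar]], data[[pvar]], p = outlier_p)
    retain <- gate$retain
  } else {
    gate <- NULL
    retain <- complete
  }
  fitdat <- data[retain, , drop = FALSE]
  if (stats::var(fitdat[[evar]]) <= 0)
    stopf("zero variance in exposure '%s' on the fitting rows", evar)

  fallback <- character()
  if (method == "ols") {
    fit <- stats::lm(stats::as.formula(paste(pvar, "~", evar)), data = fitdat)
    b <- coef(fit)
  } else {
    forms <- c(
      sprintf("%s ~ %s + (1 + %s | %s)", pvar, evar, evar, id),
      sprintf("%s ~ %s + (1 + %s || %s)", pvar, evar, evar, id),
      sprintf("%s ~ %s + (1 | %s)", pvar, evar, id)
    )
    res <- fit_lmer_ladder(forms, fitdat, reml = reml)
    fallback <- res$notes
    if (is.null(res$fit)) {
      warnf("mixed normative line: all random structures failed; falling back to OLS")
      fallback <- c(fallback, "ols")
      fit <- stats::lm(stats::as.formula(paste(pvar, "~", evar)), data = fitdat)
      method <- "ols"
      b <- coef(fit)
    } else {
      fit <- res$fit
      b <- lme4::fixef(fit)
    }
  }

  line <- structure(list(
    intercept = unname(b[1L]), slope = unname(b[2L]),
    method = if (method == "ols") "ols" else "mixed_fixed_effects",
    n_obs = nrow(fitdat),
    n_outliers_removed = if (is.null(gate)) 0L else gate$n_excluded),
    class = "normative_line")

  data$sr <- ifelse(retain,
                    data[[pvar]] - (line$intercept + line$slope * data[[evar]]),
                    NA_real_)
  data$.retained <- retain
  structure(list(line = line, data = data, fit = fit, gate = gate,
                 symptoms = pvar, exposure = evar, id = id,
                 method = method, fallback = fallback,
                 call = match.call()),
            class = "sr_fit")
}

## Try lmer formulas in order; accept the first converging fit. Warnings are
## muffled (convergence problems surface in the fit's optinfo, which
## lmer_converged inspects); errors move down the ladder.
fit_lmer_ladder <- function(forms, data, reml = TRUE) {
  notes <- character()
  for (f in forms) {
    fit <- tryCatch(
      withCallingHandlers(
        suppressMessages(lme4::lmer(stats::as.formula(f), data = data,
                                    REML = reml,
                                    control = lme4::lmerControl(
                                      check.conv.singular = "ignore"))),
        warning = function(w) invokeRestart("muffleWarning")),
      error = function(e) NULL)
    if (!is.null(fit) && lmer_converged(fit))
      return(list(fit = fit, formula = f, notes = notes))
    notes <- c(notes, sprintf("random structure '%s' did not converge", f))
  }
  list(fit = NULL, formula = NULL, notes = notes)
}

lmer_converged <- function(fit) {
  msgs <- fit@optinfo$conv$lme4$messages
  is.null(msgs) || !any(grepl("failed to converge", msgs, fixed = TRUE))
}

#' Compute SR scores for new observations against a fitted line
#'
#' @param line a \code{"normative_line"} (e.g. \code{fit$line}) or an
#'   \code{"sr_fit"}.
#' @param data data frame with exposure and symptom columns.
#' @param exposure,symptoms column names.
#' @return \code{data} with an \code{sr} column: \code{P - (b0 + b1 E)};
#'   missing E or P propagates to missing SR.
#' @export
compute_sr <- function(line, data, exposure = "E", symptoms = "P") {
  if (inherits(line, "sr_fit")) {
    exposure <- line$exposure; symptoms <- line$symptoms; line <- line$line
  }
  if (!inherits(line, "normative_line"))
    stopf("'line' must be a normative_line or sr_fit object")
  check_cols(data, c(exposure, symptoms), "compute_sr")
  data$sr <- data[[symptoms]] - (line$intercept + line$slope * data[[exposure]])
  data
}

#' Per-participant mean SR over follow-up weeks
#'
#' Averages each participant's SR scores over retained follow-up assessments,
#' excluding the baseline week. Participants without any retained follow-up
#' get \code{NA}.
#'
#' @param data data frame with id, assessment-index, and SR columns.
#' @param id,t,sr column names.
#' @param baseline_t assessment index of the baseline week (excluded).
#' @return Data frame with columns \code{id}, \code{mean_sr},
#'   \code{n_followups}.
#' @export
average_sr <- function(data, id = "id", t = "t", sr = "sr", baseline_t = 0) {
  check_cols(data, c(id, t, sr), "average_sr")
  fu <- data[data[[t]] != baseline_t & !is.na(data[[sr]]), , drop = FALSE]
  all_ids <- unique(data[[id]])
  agg <- if (nrow(fu)) {
    stats::aggregate(fu[[sr]], by = list(id = fu[[id]]),
                     FUN = function(v) c(mean(v), length(v)))
  } else NULL
  out <- data.frame(id = all_ids, mean_sr = NA_real_,
                    n_followups = 0L, stringsAsFactors = FALSE)
  if (!is.null(agg)) {
    i <- match(agg$id, out$id)
    out$mean_sr[i] <- agg$x[, 1L]
    out$n_followups[i] <- as.integer(agg$x[, 2L])
  }
  out
}

#' Curvature check: does a quadratic exposure term improve the line?
#'
#' Compares the linear normative model with one augmented by squared
#' exposure on identical rows: an F test for OLS, a likelihood-ratio
#' chi-square (models refitted by ML) for the mixed model.
#'
#' @param data data frame of fitting rows (already outlier-gated).
#' @param method \code{"ols"} or \code{"mixed"}.
#' @param exposure,symptoms,id column names.
#' @return List with \code{statistic}, \code{df}, \code{p}, \code{method}.
#' @export
test_polynomial_term <- function(data, method = c("ols", "mixed"),
                                 exposure = "E", symptoms = "P", id = "id") {
  method <- match.arg(method)
  check_cols(data, c(exposure, symptoms), "test_polynomial_term")
  data <- as.data.frame(data)
  data <- data[stats::complete.cases(data[[exposure]], data[[symptoms]]), ,
               drop = FALSE]
  data$.E2 <- data[[exposure]]^2
  if (method == "ols") {
    f1 <- stats::lm(stats::as.formula(paste(symptoms, "~", exposure)), data)
    f2 <- stats::lm(stats::as.formula(paste(symptoms, "~", exposure, "+ .E2")),
                    data)
    a <- stats::anova(f1, f2)
    list(statistic = a[2, "F"], df = c(1, a[2, "Res.Df"]),
         p = a[2, "Pr(>F)"], method = "F")
  } else {
    check_cols(data, id, "test_polynomial_term (mixed)")
    f1 <- suppressMessages(lme4::lmer(
      stats::as.formula(sprintf("%s ~ %s + (1 + %s | %s)",
                                symptoms, exposure, exposure, id)),
      data, REML = FALSE,
      control = lme4::lmerControl(check.conv.singular = "ignore")))
    f2 <- suppressMessages(lme4::lmer(
      stats::as.formula(sprintf("%s ~ %s + .E2 + (1 + %s | %s)",
                                symptoms, exposure, exposure, id)),
      data, REML = FALSE,
      control = lme4::lmerControl(check.conv.singular = "ignore")))
    a <- stats::anova(f1, f2)
    list(statistic = a[2, "Chisq"], df = a[2, "Df"],
         p = a[2, "Pr(>Chisq)"], method = "LRT")
  }
}

#' @export
print.normative_line <- function(x, ...) {
  cat(sprintf("Normative E-P line (%s): P = %.4g + %.4g E  [n = %d, %d outlier(s) gated]\n",
              x$method, x$intercept, x$slope, x$n_obs, x$n_outliers_removed))
  invisible(x)
}

#' @export
print.sr_fit <- function(x, ...) {
  cat("Stressor-reactivity fit\n")
  print(x$line)
  sr <- x$data$sr[x$data$.retained]
  cat(sprintf("  SR scores: n = %d, mean = %.4g, sd = %.4g\n",
              length(sr), mean(sr), stats::sd(sr)))
  if (length(x$fallback))
    cat("  notes:", paste(x$fallback, collapse = "; "), "\n")
  invisible(x)
}

#' @export
summary.sr_fit <- function(object, ...) {
  sr <- object$data$sr[object$data$.retained]
  out <- list(line = object$line, n = length(sr),
              sr_mean = mean(sr), sr_sd = stats::sd(sr),
              sr_quantiles = stats::quantile(sr, c(0, .25, .5, .75, 1)),
              fallback = object$fallback)
  class(out) <- "summary.sr_fit"
  out
}

#' @export
print.summary.sr_fit <- function(x, ...) {
  print(x$line)
  cat(sprintf("SR: n = %d, mean = %.4g, sd = %.4g\n", x$n, x$sr_mean, x$sr_sd))
  print(round(x$sr_quantiles, 4))
  invisible(x)
}

#' @export
coef.sr_fit <- function(object, ...) {
  c(intercept = object$line$intercept, slope = object$line$slope)
}

#' @export
predict.sr_fit <- function(object, newdata = NULL, ...) {
  E <- if (is.null(newdata)) object$data[[object$exposure]]
       else if (is.data.frame(newdata)) newdata[[object$exposure]]
       else newdata
  object$line$intercept + object$line$slope * E
}

#' @export
fitted.sr_fit <- function(object, ...) predict(object)

#' @export
residuals.sr_fit <- function(object, ...) object$data$sr

#' @export
plot.sr_fit <- function(x, ...) {
  d <- x$data
  graphics::plot(d[[x$exposure]], d[[x$symptoms]],
                 col = ifelse(d$.retained, "grey30", "red"),
                 pch = ifelse(d$.retained, 1, 4),
                 xlab = "stressor exposure E",
                 ylab = "mental health problems P", ...)
  graphics::abline(x$line$intercept, x$line$slope, col = "blue", lwd = 2)
  invisible(x)
}
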