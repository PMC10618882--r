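#' Bonferroni-adjusted significance threshold
#'
#' @param alpha nominal alpha in (0, 1).
#' @param k number of primary hypotheses sharing it (>= 1).
#' @return \code{alpha / k}.
#' @examples
#' bonferroni_threshold(0.05, 2)  # 0.025
#' @export
bonferroni_threshold <- function(alpha, k) {
  if (!is.numeric(alpha) || length(alpha) != 1L || alpha <= 0 || alpha >= 1)
    stopf("'alpha' must lie in (0, 1)")
  if (!is.numeric(k) || length(k) != 1L || is.na(k) || k < 1)
    stopf("'k' must be >= 1")
  alpha / k
}

#' Diagnosis contrast on SR scores (pooled-variance two-sample t)
#'
#' Compares SR between participants without and with a mental health
#' diagnosis using Student's pooled-variance t with
#' \code{df = n1 + n2 - 2}. Either raw data (\code{sr} + binary
#' \code{group}) or the six summary statistics may be supplied, so the
#' contrast can be recomputed from published group summaries alone.
#'
#' @param sr numeric SR scores (raw-data interface).
#' @param group binary flag aligned with \code{sr}; the \code{FALSE}/0 level
#'   is group 1.
#' @param n1,mean1,sd1,n2,mean2,sd2 summary-statistic interface.
#' @return List with per-group n/mean/sd, \code{t}, \code{df}, \code{p}
#'   (two-tailed).
#' @examples
#' diagnosis_contrast(n1 = 374, mean1 = -0.15, sd1 = 0.97,
#'                    n2 = 184, mean2 = 0.29, sd2 = 1.01)
#' @export
diagnosis_contrast <- function(sr = NULL, group = NULL,
                               n1 = NULL, mean1 = NULL, sd1 = NULL,
                               n2 = NULL, mean2 = NULL, sd2 = NULL) {
  if (!is.null(sr)) {
    if (is.null(group) || length(group) != length(sr))
      stopf("'group' must accompany 'sr' with equal length")
    ok <- stats::complete.cases(sr, group)
    sr <- sr[ok]; group <- as.logical(group[ok])
    g1 <- sr[!group]; g2 <- sr[group]
    if (length(g1) < 2L || length(g2) < 2L)
      stopf("each group needs at least 2 observations")
    n1 <- length(g1); mean1 <- mean(g1); sd1 <- stats::sd(g1)
    n2 <- length(g2); mean2 <- mean(g2); sd2 <- stats::sd(g2)
  }
  if (any(vapply(list(n1, mean1, sd1, n2, mean2, sd2), is.null, TRUE)))
    stopf("supply either (sr, group) or all six summary statistics")
  if (n1 < 2 || n2 < 2) stopf("each group needs at least 2 observations")
  df <- n1 + n2 - 2
  sp2 <- ((n1 - 1) * sd1^2 + (n2 - 1) * sd2^2) / df
  if (sp2 <= 0)
    stopf("zero pooled variance: the t statistic is undefined")
  tval <- (mean1 - mean2) / sqrt(sp2 * (1 / n1 + 1 / n2))
  list(n1 = n1, mean1 = mean1, sd1 = sd1,
       n2 = n2, mean2 = mean2, sd2 = sd2,
       t = tval, df = df, p = 2 * stats::pt(-abs(tval), df))
}

#' Run the full outcome-based resilience pipeline
#'
#' Orchestrates the stages end to end on a synthetic cohort (or supplied
#' tables): spacing and completion filters, cross-sectional (OLS) and
#' longitudinal (mixed-model) normative lines with Mahalanobis gating, SR
#' scoring, likelihood-ratio covariate screens, per-RF cross-sectional and
#' prospective regressions, contemporaneous / lagged / autoregressive
#' within-person models, exposure-to-RF lagged models, ICCs, the three
#' mediation analyses, and the diagnosis contrast. All randomness (cohort
#' generation and Monte Carlo mediation CIs) is governed by \code{seed}.
#'
#' @param sim a \code{\link{sim_config}}; ignored when \code{data} is given.
#' @param seed master seed.
#' @param data optional list with \code{baseline} and \code{weekly} tables
#'   (as produced by \code{\link{simulate_cohort}} / \code{\link{load_panel}}).
#' @param candidates candidate covariates for the screens.
#' @param alpha nominal two-tailed alpha.
#' @param bonferroni_k primary-hypothesis count for the lagged
#'   positive-appraisal tests.
#' @param mc_draws Monte Carlo draws for mediation CIs.
#' @param min_followups completion-filter threshold.
#' @param out_dir if non-\code{NULL}, results are written there as CSV/JSON
#'   (per-hypothesis tables, normative lines, drop log, run manifest).
#' @return An object of class \code{"sr_pipeline"}: a named list of all stage
#'   results.
#' @export
run_pipeline <- function(sim = sim_config(), seed = 1, data = NULL,
                         candidates = c("education", "general_health",
                                        "diagnosis", "risk_group", "opinion"),
                         alpha = 0.05, bonferroni_k = 2, mc_draws = 1e5,
                         min_followups = 4, out_dir = NULL) {
  if (is.null(data)) {
    cohort <- simulate_cohort(sim, seed = seed)
    baseline <- cohort$baseline; weekly <- cohort$weekly
    truth <- cohort$truth
  } else {
    if (!all(c("baseline", "weekly") %in% names(data)))
      stopf("stage input: 'data' must contain 'baseline' and 'weekly' tables")
    baseline <- data$baseline; weekly <- data$weekly; truth <- NULL
    cohort <- NULL
  }
  check_cols(weekly, c("id", "t", "E", "P"), "pipeline weekly table")
  check_cols(baseline, "id", "pipeline baseline table")

  ## --- sample preparation -------------------------------------------------
  sp <- filter_followup_spacing(weekly)
  weekly_ret <- sp$retained
  completion <- filter_completion(weekly_ret, min_followups = min_followups)
  long_ids <- completion$id[completion$in_longitudinal]

  rfs_style <- grep("_style$", names(baseline), value = TRUE)
  rfs_mode <- grep("_mode$", names(weekly), value = TRUE)
  covar_cols <- intersect(c("age", "gender", "language", candidates),
                          names(baseline))

  ## --- cross-sectional SR (baseline week, OLS line) -----------------------
  base_week <- weekly_ret[weekly_ret$t == 0, , drop = FALSE]
  cross <- merge(base_week[c("id", "t", "E", "P", rfs_mode)],
                 baseline[c("id", covar_cols, rfs_style)], by = "id")
  fit_cross <- sr_fit(P ~ E, cross, method = "ols")
  cross$sr <- fit_cross$data$sr[match(cross$id, fit_cross$data$id)]
  poly_cross <- test_polynomial_term(
    fit_cross$data[fit_cross$data$.retained, ], method = "ols")

  ## --- longitudinal SR (all retained weeks, mixed line) -------------------
  long_weekly <- weekly_ret[weekly_ret$id %in% long_ids, , drop = FALSE]
  h3 <- h4 <- h4_ar <- h5 <- icc_tab <- med_h3 <- NULL
  fit_long <- NULL; poly_long <- NULL; screen_long <- NULL
  h2_tab <- NULL; med_h2 <- NULL; mean_sr <- NULL
  if (length(long_ids) >= 10) {
    fit_long <- sr_fit(P ~ E, long_weekly, id = "id", method = "mixed")
    long_sr <- fit_long$data
    long_sr <- merge(long_sr, baseline[c("id", covar_cols)], by = "id")
    poly_long <- test_polynomial_term(
      fit_long$data[fit_long$data$.retained, ], method = "mixed")

    mean_sr <- average_sr(long_sr)
    h2_data <- merge(merge(mean_sr, baseline, by = "id"),
                     cross[c("id", setdiff(rfs_mode, names(baseline)))],
                     by = "id", all.x = TRUE)

    screen_long <- screen_covariates(long_sr, outcome = "sr",
                                     candidates = intersect(candidates,
                                                            names(long_sr)),
                                     sample_kind = "long")

    h2_tab <- run_h2(h2_data, rfs = c(rfs_style, intersect(rfs_mode,
                                                           names(h2_data))),
                     outcome = "mean_sr", covariates = screen_long)

    ## weekly within-person models
    for (rf in rfs_mode) {
      h3_k <- fit_contemporaneous(long_sr, rf, covariates = screen_long)
      h4_k <- fit_lagged_rf_sr(long_sr, rf, covariates = screen_long,
                               alpha = alpha,
                               bonferroni_k = if (grepl("^PA", rf))
                                 bonferroni_k else 1)
      h5_k <- fit_lagged_e_rf(long_sr, rf, covariates = screen_long)
      icc_k <- icc(long_sr, rf)
      h3 <- rbind(h3, wb_row(h3_k, rf))
      h4 <- rbind(h4, cbind(wb_row(h4_k, rf),
                            alpha_adjusted = h4_k$alpha_adjusted,
                            significant = h4_k$significant))
      h5 <- rbind(h5, wb_row(h5_k, rf))
      icc_tab <- rbind(icc_tab,
                       data.frame(rf = rf, icc = icc_k$icc,
                                  var_between = icc_k$var_between,
                                  var_within = icc_k$var_within,
                                  flag = icc_k$flag,
                                  stringsAsFactors = FALSE))
      ## autoregressive follow-up where the raw lagged effect is significant
      if (isTRUE(h4_k$significant)) {
        ar_k <- fit_autoregressive_followup(long_sr, rf,
                                            covariates = screen_long)
        h4_ar <- rbind(h4_ar, wb_row(ar_k, rf))
      }
    }
    if (all(c("PSS_mode", "PA_mode") %in% rfs_mode))
      med_h3 <- multilevel_mediation(long_sr, x = "PSS_mode", m = "PA_mode",
                                     y = "sr", covariates = screen_long,
                                     draws = mc_draws, seed = seed + 3L)
  }

  ## --- covariate screen + H1 on the cross-sectional sample ----------------
  screen_cross <- screen_covariates(cross, outcome = "sr",
                                    candidates = intersect(candidates,
                                                           names(cross)),
                                    sample_kind = "cross")
  h1_rfs <- c(rfs_style, intersect(rfs_mode, names(cross)))
  h1_tab <- run_h1(cross, rfs = h1_rfs, covariates = screen_cross)

  med_h1 <- if (all(c("PSS_style", "PA_style") %in% names(cross)))
    baron_kenny(cross, x = "PSS_style", m = "PA_style", y = "sr",
                covariates = screen_cross, draws = mc_draws,
                seed = seed + 1L)
  if (!is.null(mean_sr)) {
    h2_med_data <- merge(mean_sr, baseline, by = "id")
    med_h2 <- if (all(c("PSS_style", "PA_style") %in% names(h2_med_data)))
      baron_kenny(h2_med_data, x = "PSS_style", m = "PA_style", y = "mean_sr",
                  covariates = screen_long, draws = mc_draws,
                  seed = seed + 2L)
  }

  ## --- diagnosis contrast + tertile subsets -------------------------------
  contrast <- if ("diagnosis" %in% names(cross)) {
    zsr <- (cross$sr - mean(cross$sr, na.rm = TRUE)) /
      stats::sd(cross$sr, na.rm = TRUE)
    diagnosis_contrast(zsr, cross$diagnosis)
  }
  mean_e <- stats::aggregate(list(mean_E = weekly_ret$E),
                             by = list(id = weekly_ret$id), FUN = mean)
  tertile_ids <- top_tertile_subset(mean_e)

  bundle <- structure(list(
    seed = seed, config = if (is.null(data)) sim else NULL, truth = truth,
    drop_log = sp$drop_log, completion = completion,
    n_cross = nrow(cross), n_long = length(long_ids),
    line_cross = fit_cross$line, line_long = if (!is.null(fit_long))
      fit_long$line,
    poly_cross = poly_cross, poly_long = poly_long,
    sr_cross = cross[c("id", "E", "P", "sr")],
    sr_long = if (!is.null(fit_long))
      fit_long$data[c("id", "t", "E", "P", "sr")],
    mean_sr = mean_sr,
    screen_cross = screen_cross, screen_long = screen_long,
    h1 = h1_tab, h2 = h2_tab, h3 = h3, h4 = h4, h4_ar = h4_ar, h5 = h5,
    icc = icc_tab,
    mediation_h1 = med_h1, mediation_h2 = med_h2, mediation_h3 = med_h3,
    diagnosis = contrast, tertile_ids = tertile_ids,
    alpha = alpha, alpha_lagged_primary = bonferroni_threshold(alpha,
                                                               bonferroni_k)),
    class = "sr_pipeline")
  if (!is.null(out_dir)) write_bundle(bundle, out_dir)
  bundle
}

wb_row <- function(x, rf) {
  data.frame(rf = rf,
             beta_within = x$within$beta_std, se_within = x$within$se,
             ci_within_lower = x$within$ci_lower,
             ci_within_upper = x$within$ci_upper, p_within = x$within$p,
             beta_between = x$between$beta_std, se_between = x$between$se,
             ci_between_lower = x$between$ci_lower,
             ci_between_upper = x$between$ci_upper, p_between = x$between$p,
             n_participants = x$n_participants, n_obs = x$n_obs,
             structure = x$structure, stringsAsFactors = FALSE)
}

#' @export
print.sr_pipeline <- function(x, ...) {
  cat("Outcome-based resilience pipeline\n")
  cat(sprintf("  cross-sectional n = %d; longitudinal n = %d\n",
              x$n_cross, x$n_long))
  print(x$line_cross)
  if (!is.null(x$line_long)) print(x$line_long)
  if (!is.null(x$h1)) {
    cat("  cross-sectional RF associations (H1):\n")
    print(x$h1[c("predictor", "beta_std", "se", "p", "n")], digits = 3)
  }
  if (!is.null(x$diagnosis))
    cat(sprintf("  diagnosis contrast: t(%d) = %.2f, p = %.3g\n",
                x$diagnosis$df, x$diagnosis$t, x$diagnosis$p))
  invisible(x)
}

## Write the results bundle as plain-text files plus a run manifest.
write_bundle <- function(bundle, out_dir) {
  if (!dir.exists(out_dir)) dir.create(out_dir, recursive = TRUE)
  wcsv <- function(obj, name) {
    if (!is.null(obj) && is.data.frame(obj))
      write.csv(obj, file.path(out_dir, name), row.names = FALSE, na = "")
  }
  wcsv(bundle$h1, "h1.csv"); wcsv(bundle$h2, "h2.csv")
  wcsv(bundle$h3, "h3.csv"); wcsv(bundle$h4, "h4.csv")
  wcsv(bundle$h4_ar, "h4_autoregressive.csv"); wcsv(bundle$h5, "h5.csv")
  wcsv(bundle$icc, "icc.csv")
  wcsv(bundle$sr_cross, "sr_cross.csv"); wcsv(bundle$sr_long, "sr_long.csv")
  wcsv(bundle$drop_log, "drop_log.csv")
  wcsv(bundle$completion, "completion.csv")
  lines <- list(cross = unclass(bundle$line_cross),
                longitudinal = if (!is.null(bundle$line_long))
                  unclass(bundle$line_long))
  jsonlite::write_json(lines, file.path(out_dir, "normative_lines.json"),
                       auto_unbox = TRUE, digits = NA, na = "null")
  manifest <- list(seed = bundle$seed,
                   n_cross = bundle$n_cross, n_long = bundle$n_long,
                   alpha = bundle$alpha,
                   alpha_lagged_primary = bundle$alpha_lagged_primary,
                   r_version = as.character(getRversion()),
                   timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S"))
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(out_dir)
}
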