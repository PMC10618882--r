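#' Specification of one simulated resilience factor
#'
#' Describes how a resilience factor (RF) is generated: a stable person-level
#' component (SD \code{between_sd}) plus a weekly AR(1) fluctuation (stationary
#' SD \code{within_sd}, autocorrelation \code{ar1}). The implied intraclass
#' correlation is \code{between_sd^2 / (between_sd^2 + within_sd^2)}. Effects
#' on stressor reactivity are expressed in symptom units per SD of the
#' corresponding component: \code{effect_between} per SD of the stable
#' component, \code{effect_within} (same week) and \code{effect_lagged}
#' (previous week) per SD of the weekly fluctuation. \code{e_effect_within}
#' lets standardized weekly stressor exposure drive the RF fluctuation
#' contemporaneously (used to emulate stress-inoculation-style dynamics).
#'
#' @param name short RF label, e.g. \code{"PA"}.
#' @param baseline logical; is a baseline style/trait measure emitted
#'   (column \code{<name>_style})?
#' @param weekly logical; is a weekly mode measure emitted
#'   (column \code{<name>_mode})?
#' @param mean person-level mean of the RF scale.
#' @param between_sd,within_sd SDs of the stable and fluctuating components.
#' @param ar1 within-person autocorrelation of the weekly fluctuation,
#'   in (-1, 1).
#' @param style_noise_sd measurement noise SD added to the baseline style.
#' @param effect_between,effect_within,effect_lagged effects on weekly
#'   symptoms (hence SR), see Details.
#' @param e_effect_within effect of standardized same-week exposure on the
#'   RF fluctuation.
#' @return An object of class \code{"rf_spec"}.
#' @export
rf_spec <- function(name, baseline = TRUE, weekly = FALSE, mean = 3,
                    between_sd = 0.87, within_sd = 0.5, ar1 = 0.3,
                    style_noise_sd = 0,
                    effect_between = 0, effect_within = 0, effect_lagged = 0,
                    e_effect_within = 0) {
  if (!is.character(name) || length(name) != 1L || !nzchar(name))
    stopf("configuration error: 'name' must be a non-empty string")
  check_nonneg(between_sd, "between_sd")
  check_nonneg(within_sd, "within_sd")
  check_nonneg(style_noise_sd, "style_noise_sd")
  if (!is.numeric(ar1) || abs(ar1) >= 1)
    stopf("configuration error: 'ar1' must lie in (-1, 1)")
  structure(list(name = name, baseline = isTRUE(baseline),
                 weekly = isTRUE(weekly), mean = mean,
                 between_sd = between_sd, within_sd = within_sd, ar1 = ar1,
                 style_noise_sd = style_noise_sd,
                 effect_between = effect_between,
                 effect_within = effect_within,
                 effect_lagged = effect_lagged,
                 e_effect_within = e_effect_within),
            class = "rf_spec")
}

#' Specification of a generated mediation triple
#'
#' Builds a true indirect pathway x -> m -> SR into the cohort. At
#' \code{level = "between"} the stable component of RF \code{m} is constructed
#' as \code{a} times the standardized stable component of \code{x} plus
#' independent noise, and the stable components feed symptoms with weights
#' \code{b} (via m) and \code{c_prime} (direct). At \code{level = "within"}
#' the same construction is applied to the weekly fluctuations. The
#' mediation weights replace the corresponding \code{effect_between} /
#' \code{effect_within} entries of \code{x} and \code{m}.
#'
#' @param x,m RF names (must exist in the config's \code{rf_specs}).
#' @param a standardized x -> m path.
#' @param b m -> symptom weight (symptom units per component SD).
#' @param c_prime direct x -> symptom weight.
#' @param level \code{"between"} (stable components) or \code{"within"}
#'   (weekly fluctuations).
#' @return An object of class \code{"mediation_spec"}.
#' @export
mediation_spec <- function(x = "PSS", m = "PA", a = 0.35, b = -1,
                           c_prime = -0.6, level = c("between", "within")) {
  level <- match.arg(level)
  if (abs(a) > 1)
    stopf("configuration error: 'a' must lie in [-1, 1] (standardized path)")
  structure(list(x = x, m = m, a = a, b = b, c_prime = c_prime, level = level),
            class = "mediation_spec")
}

default_rf_specs <- function() {
  list(
    rf_spec("PA",  baseline = TRUE,  weekly = TRUE,  effect_between = -1,
            effect_within = -0.8),
    rf_spec("PAC", baseline = TRUE,  weekly = TRUE,  effect_between = -1,
            effect_within = -0.8),
    rf_spec("OPT", baseline = TRUE,  weekly = FALSE, effect_between = -1),
    rf_spec("GSE", baseline = TRUE,  weekly = TRUE,  effect_between = -1,
            effect_within = -0.8),
    rf_spec("REC", baseline = TRUE,  weekly = FALSE, effect_between = -1),
    rf_spec("PSS", baseline = TRUE,  weekly = TRUE,  effect_between = -1),
    rf_spec("CSS", baseline = TRUE,  weekly = FALSE, effect_between = 0),
    rf_spec("BC",  baseline = TRUE,  weekly = TRUE,  effect_between = 0),
    rf_spec("NEU", baseline = TRUE,  weekly = FALSE, effect_between = 1)
  )
}

#' Configuration of the synthetic cohort generator
#'
#' Defines the generating model for a cohort with one baseline assessment and
#' \code{n_followups} weekly follow-ups. Weekly symptoms P follow
#' \deqn{P_{it} = b_0 + (b_1 + u_{1i}) E_{it} + u_{0i} + g_{it} + \epsilon_{it}}
#' where \eqn{E_{it}} is the summed stressor severity, \eqn{(u_{0i}, u_{1i})}
#' are participant deviations from the normative exposure-symptom line, and
#' \eqn{g_{it}} collects RF, mediation, and diagnosis contributions. The true
#' stressor-reactivity score of an observation is everything above the
#' normative line: \eqn{u_{0i} + u_{1i} E_{it} + g_{it} + \epsilon_{it}}.
#'
#' Stressor items occur independently with probability
#' \code{occurrence_prob}; given occurrence, the severity (1-5) is drawn from
#' \code{severity_probs}. Exposure E is the item sum. Defaults mirror the
#' cohort structure this package targets: 558 participants, 5 weekly
#' follow-ups after baseline, 40 checklist stressors, a diagnosis prevalence
#' of one third with a positive SR shift, per-week dropout of 0.2, and RF
#' intraclass correlations near 0.75.
#'
#' @param n_participants,n_followups,n_stressor_items cohort dimensions.
#' @param ep_intercept,ep_slope normative exposure-symptom line.
#' @param sd_random_intercept,sd_random_slope,re_correlation participant
#'   random deviations from the line (correlated bivariate normal).
#' @param residual_sd week-level symptom noise SD.
#' @param rf_specs list of \code{\link{rf_spec}} objects.
#' @param mediation a \code{\link{mediation_spec}} or \code{NULL}.
#' @param dropout_prob_per_week probability of (monotone) dropout before each
#'   follow-up.
#' @param date_jitter_days follow-up dates deviate from the 7-day schedule by
#'   an integer drawn uniformly from \code{-date_jitter_days ..
#'   +date_jitter_days}.
#' @param diagnosis_prevalence,diagnosis_sr_shift prevalence of a mental
#'   health diagnosis flag and the symptom shift it adds at every week.
#' @param occurrence_prob,severity_probs stressor item mixture (see Details).
#' @param ghq_items if \code{TRUE}, round P into 0-36 and emit 12 item
#'   columns (0-3 each) whose sum equals P exactly.
#' @param start_date baseline calendar date.
#' @return An object of class \code{"sim_config"}.
#' @seealso \code{\link{simulate_cohort}}
#' @export
sim_config <- function(n_participants = 558, n_followups = 5,
                       n_stressor_items = 40,
                       ep_intercept = 8, ep_slope = 0.08,
                       sd_random_intercept = 2, sd_random_slope = 0.02,
                       re_correlation = 0, residual_sd = 4,
                       rf_specs = default_rf_specs(),
                       mediation = mediation_spec(),
                       dropout_prob_per_week = 0.2, date_jitter_days = 1,
                       diagnosis_prevalence = 0.33, diagnosis_sr_shift = 2,
                       occurrence_prob = 0.35,
                       severity_probs = c(0.30, 0.25, 0.20, 0.15, 0.10),
                       ghq_items = FALSE,
                       start_date = as.Date("2020-04-06")) {
  n_participants <- check_count(n_participants, "n_participants")
  n_followups <- check_count(n_followups, "n_followups")
  n_stressor_items <- check_count(n_stressor_items, "n_stressor_items")
  check_nonneg(sd_random_intercept, "sd_random_intercept")
  check_nonneg(sd_random_slope, "sd_random_slope")
  check_nonneg(residual_sd, "residual_sd")
  check_prob(dropout_prob_per_week, "dropout_prob_per_week")
  check_prob(diagnosis_prevalence, "diagnosis_prevalence")
  check_prob(occurrence_prob, "occurrence_prob")
  if (abs(re_correlation) > 1)
    stopf("configuration error: 're_correlation' must lie in [-1, 1]")
  date_jitter_days <- check_count(date_jitter_days, "date_jitter_days", min = 0L)
  if (length(severity_probs) != 5L || any(severity_probs < 0) ||
      abs(sum(severity_probs) - 1) > 1e-8)
    stopf("configuration error: 'severity_probs' must be 5 probabilities summing to 1")
  if (!length(rf_specs) || !all(vapply(rf_specs, inherits, TRUE, "rf_spec")))
    stopf("configuration error: 'rf_specs' must be a list of rf_spec objects")
  nm <- vapply(rf_specs, `[[`, "", "name")
  if (anyDuplicated(nm))
    stopf("configuration error: duplicate RF name in 'rf_specs'")
  names(rf_specs) <- nm
  ## the default mediation spec only applies when its RFs are present
  if (missing(mediation) && !is.null(mediation) &&
      !all(c(mediation$x, mediation$m) %in% nm))
    mediation <- NULL
  if (!is.null(mediation)) {
    if (!inherits(mediation, "mediation_spec"))
      stopf("configuration error: 'mediation' must be a mediation_spec or NULL")
    if (!all(c(mediation$x, mediation$m) %in% nm))
      stopf("configuration error: mediation RFs '%s', '%s' must appear in rf_specs",
            mediation$x, mediation$m)
  }
  structure(list(
    n_participants = n_participants, n_followups = n_followups,
    n_stressor_items = n_stressor_items,
    ep_intercept = ep_intercept, ep_slope = ep_slope,
    sd_random_intercept = sd_random_intercept,
    sd_random_slope = sd_random_slope, re_correlation = re_correlation,
    residual_sd = residual_sd, rf_specs = rf_specs, mediation = mediation,
    dropout_prob_per_week = dropout_prob_per_week,
    date_jitter_days = date_jitter_days,
    diagnosis_prevalence = diagnosis_prevalence,
    diagnosis_sr_shift = diagnosis_sr_shift,
    occurrence_prob = occurrence_prob, severity_probs = severity_probs,
    ghq_items = isTRUE(ghq_items), start_date = as.Date(start_date)),
    class = "sim_config")
}

#' @export
print.sim_config <- function(x, ...) {
  cat("Synthetic cohort configuration\n")
  cat(sprintf("  participants: %d, follow-ups: %d, stressor items: %d\n",
              x$n_participants, x$n_followups, x$n_stressor_items))
  cat(sprintf("  normative line: P = %.3g + %.3g E (u0 sd %.3g, u1 sd %.3g, resid sd %.3g)\n",
              x$ep_intercept, x$ep_slope, x$sd_random_intercept,
              x$sd_random_slope, x$residual_sd))
  cat(sprintf("  RFs: %s\n", paste(names(x$rf_specs), collapse = ", ")))
  if (!is.null(x$mediation))
    cat(sprintf("  mediation (%s): %s -> %s -> SR, a=%.3g b=%.3g c'=%.3g\n",
                x$mediation$level, x$mediation$x, x$mediation$m,
                x$mediation$a, x$mediation$b, x$mediation$c_prime))
  invisible(x)
}

## First two moments of weekly exposure E under the item mixture.
e_moments <- function(config) {
  s <- 1:5
  p <- config$severity_probs
  m1 <- config$occurrence_prob * sum(s * p)
  m2 <- config$occurrence_prob * sum(s^2 * p)
  v <- m2 - m1^2
  list(mean = config$n_stressor_items * m1,
       var = config$n_stressor_items * v)
}

#' Draw stressor severity ratings
#'
#' Each item independently "occurs" with probability \code{occurrence_prob};
#' an occurring item receives a severity in 1-5 drawn from
#' \code{severity_probs}, a non-occurring item is rated 0. Exposure E is the
#' row sum.
#'
#' @param n number of participant-weeks to draw.
#' @param n_items number of checklist items.
#' @param occurrence_prob per-item occurrence probability.
#' @param severity_probs probabilities of severities 1-5 given occurrence.
#' @return Integer matrix \code{n x n_items} with entries in 0-5.
#' @export
draw_stressor_severities <- function(n, n_items, occurrence_prob = 0.35,
                                     severity_probs = c(0.30, 0.25, 0.20, 0.15, 0.10)) {
  check_count(n, "n")
  check_count(n_items, "n_items")
  check_prob(occurrence_prob, "occurrence_prob")
  occ <- matrix(runif(n * n_items) < occurrence_prob, n, n_items)
  sev <- matrix(sample(1:5, n * n_items, replace = TRUE, prob = severity_probs),
                n, n_items)
  out <- sev * occ
  storage.mode(out) <- "integer"
  out
}

## Simulate n AR(1) paths over columns t = -1..Tf (stationary sd `wsd`),
## optionally driven by a standardized exposure matrix (columns t = 0..Tf).
sim_ar1 <- function(n, Tf, wsd, rho, gamma = 0, ze = NULL) {
  w <- matrix(0, n, Tf + 2L)
  if (wsd == 0 && gamma == 0) return(w)
  innov_sd <- wsd * sqrt(1 - rho^2)
  w[, 1L] <- rnorm(n, 0, wsd)
  for (t in 0:Tf) {
    drive <- if (gamma != 0 && !is.null(ze)) gamma * ze[, t + 1L] else 0
    w[, t + 2L] <- rho * w[, t + 1L] + drive + rnorm(n, 0, innov_sd)
  }
  w
}

## Split an integer total 0..36 into 12 items of 0..3 summing exactly to it.
split_ghq_items <- function(total) {
  t(vapply(total, function(p) {
    it <- integer(12)
    if (p > 0) {
      slots <- sample(rep(1:12, each = 3L), p)
      tab <- tabulate(slots, nbins = 12L)
      it <- it + tab
    }
    it
  }, integer(12)))
}

#' Generate a synthetic cohort with known ground truth
#'
#' Simulates one baseline record per participant and one record per retained
#' participant-week under the generating model described in
#' \code{\link{sim_config}}. Assessment index \code{t = 0} is the baseline
#' week (exposure and symptoms are assessed there too); follow-ups are
#' scheduled 7 days apart with integer date jitter; dropout is monotone.
#'
#' @param config a \code{\link{sim_config}}.
#' @param seed integer seed; identical \code{(config, seed)} pairs give
#'   identical tables.
#' @return A list of class \code{"synth_cohort"} with elements
#'   \describe{
#'     \item{baseline}{one row per participant: demographics, covariates,
#'       diagnosis flag, and RF style scores (\code{<rf>_style}).}
#'     \item{weekly}{long table, one row per retained participant-week:
#'       \code{id}, \code{t}, \code{date}, stressor item columns, \code{E},
#'       \code{P}, RF mode scores (\code{<rf>_mode}).}
#'     \item{truth}{ground truth: the normative line, per-participant random
#'       effects, and the true standardized estimands of the downstream
#'       models (see \code{\link{ground_truth}}).}
#'   }
#' @export
simulate_cohort <- function(config, seed = NULL) {
  if (!inherits(config, "sim_config"))
    stopf("configuration error: 'config' must be a sim_config object")
  with_seed(seed, {
    n <- config$n_participants
    Tf <- config$n_followups
    n_occ <- Tf + 1L
    em <- e_moments(config)

    ## demographics / covariates
    age <- pmin(pmax(round(rnorm(n, 32, 12)), 18), 71)
    gender <- sample(c("female", "male"), n, TRUE, prob = c(0.76, 0.24))
    language <- sample(c("de", "en", "other"), n, TRUE, prob = c(0.6, 0.25, 0.15))
    education <- sample(1:5, n, TRUE, prob = c(0.05, 0.15, 0.30, 0.30, 0.20))
    general_health <- sample(1:5, n, TRUE, prob = c(0.02, 0.08, 0.25, 0.40, 0.25))
    risk_group <- rbinom(n, 1, 0.25)
    opinion <- sample(1:5, n, TRUE, prob = c(0.05, 0.15, 0.30, 0.30, 0.20))
    diagnosis <- rbinom(n, 1, config$diagnosis_prevalence)

    ## exposure items per occasion
    sev <- lapply(seq_len(n_occ), function(k)
      draw_stressor_severities(n, config$n_stressor_items,
                               config$occurrence_prob, config$severity_probs))
    E <- vapply(sev, rowSums, numeric(n))           # n x n_occ, t = 0..Tf
    sdE <- sqrt(em$var)
    zE <- if (sdE > 0) (E - em$mean) / sdE else E * 0

    ## RF latents: stable component m, AR(1) fluctuation w (t = -1..Tf)
    med <- config$mediation
    rfs <- config$rf_specs
    m_lat <- list(); w_lat <- list()
    for (k in names(rfs)) {
      s <- rfs[[k]]
      m_lat[[k]] <- s$mean + rnorm(n, 0, s$between_sd)
      w_lat[[k]] <- sim_ar1(n, Tf, s$within_sd, s$ar1,
                            gamma = s$e_effect_within, ze = zE)
    }
    if (!is.null(med)) {
      sx <- rfs[[med$x]]; sm <- rfs[[med$m]]
      if (med$level == "between") {
        zx <- if (sx$between_sd > 0) (m_lat[[med$x]] - sx$mean) / sx$between_sd
              else rep(0, n)
        m_lat[[med$m]] <- sm$mean + sm$between_sd *
          (med$a * zx + sqrt(1 - med$a^2) * rnorm(n))
      } else {
        a_eff <- if (sx$within_sd > 0) med$a * sm$within_sd / sx$within_sd else 0
        w_lat[[med$m]] <- a_eff * w_lat[[med$x]] +
          sqrt(1 - med$a^2) * sim_ar1(n, Tf, sm$within_sd, sm$ar1)
      }
    }

    ## symptom contributions g_it (n x n_occ), using effective weights
    eff <- effective_effects(config)
    g <- matrix(0, n, n_occ)
    for (k in names(rfs)) {
      s <- rfs[[k]]
      e <- eff[[k]]
      zb <- if (s$between_sd > 0) (m_lat[[k]] - s$mean) / s$between_sd else rep(0, n)
      zw <- if (s$within_sd > 0) w_lat[[k]] / s$within_sd else w_lat[[k]] * 0
      for (t in 0:Tf) {
        g[, t + 1L] <- g[, t + 1L] + e$between * zb +
          e$within * zw[, t + 2L] + e$lagged * zw[, t + 1L]
      }
    }
    g <- g + config$diagnosis_sr_shift * diagnosis

    ## random deviations from the normative line
    rho <- config$re_correlation
    u0 <- rnorm(n, 0, config$sd_random_intercept)
    u1 <- if (config$sd_random_slope > 0)
      config$sd_random_slope *
        (rho * u0 / max(config$sd_random_intercept, .Machine$double.eps) +
           sqrt(1 - rho^2) * rnorm(n))
    else rep(0, n)

    P <- config$ep_intercept + config$ep_slope * E + u0 + u1 * E + g +
      matrix(rnorm(n * n_occ, 0, config$residual_sd), n, n_occ)

    ## retention: monotone dropout before each follow-up
    present <- matrix(TRUE, n, n_occ)
    for (t in seq_len(Tf)) {
      present[, t + 1L] <- present[, t] &
        (runif(n) >= config$dropout_prob_per_week)
    }

    ## dates: baseline staggered over a week; follow-ups jittered
    j <- config$date_jitter_days
    date0 <- config$start_date + sample(0:6, n, TRUE)
    dates <- matrix(as.integer(date0), n, n_occ)
    for (t in seq_len(Tf)) {
      jit <- if (j > 0) sample(-j:j, n, TRUE) else 0L
      dates[, t + 1L] <- as.integer(date0) + 7L * t + jit
    }

    ## assemble tables
    ids <- sprintf("P%04d", seq_len(n))
    styles <- list()
    for (k in names(rfs)) {
      s <- rfs[[k]]
      if (s$baseline)
        styles[[paste0(k, "_style")]] <-
          m_lat[[k]] + rnorm(n, 0, s$style_noise_sd)
    }
    baseline <- data.frame(id = ids, date = as.Date(dates[, 1L], origin = "1970-01-01"),
                           age = age, gender = gender, language = language,
                           education = education, general_health = general_health,
                           risk_group = risk_group, opinion = opinion,
                           diagnosis = diagnosis, stringsAsFactors = FALSE)
    for (nm in names(styles)) baseline[[nm]] <- styles[[nm]]

    weekly_rows <- vector("list", n_occ)
    item_names <- sprintf("stress_%02d", seq_len(config$n_stressor_items))
    for (t in 0:Tf) {
      keep <- present[, t + 1L]
      if (!any(keep)) next
      d <- data.frame(id = ids[keep], t = t,
                      date = as.Date(dates[keep, t + 1L], origin = "1970-01-01"),
                      stringsAsFactors = FALSE)
      sev_t <- sev[[t + 1L]][keep, , drop = FALSE]
      colnames(sev_t) <- item_names
      d <- cbind(d, as.data.frame(sev_t))
      d$E <- E[keep, t + 1L]
      Pt <- P[keep, t + 1L]
      if (config$ghq_items) {
        Pint <- pmin(pmax(round(Pt), 0L), 36L)
        gh <- split_ghq_items(Pint)
        colnames(gh) <- sprintf("ghq_%02d", 1:12)
        d$P <- as.integer(Pint)
        d <- cbind(d, as.data.frame(gh))
      } else d$P <- Pt
      for (k in names(rfs)) {
        if (rfs[[k]]$weekly)
          d[[paste0(k, "_mode")]] <- m_lat[[k]][keep] + w_lat[[k]][keep, t + 2L]
      }
      weekly_rows[[t + 1L]] <- d
    }
    weekly <- do.call(rbind, weekly_rows)
    weekly <- weekly[order(weekly$id, weekly$t), , drop = FALSE]
    rownames(weekly) <- NULL

    truth <- ground_truth(config)
    truth$random_effects <- data.frame(id = ids, u0 = u0, u1 = u1,
                                       stringsAsFactors = FALSE)
    structure(list(baseline = baseline, weekly = weekly, truth = truth,
                   config = config),
              class = "synth_cohort")
  })
}

#' @export
print.synth_cohort <- function(x, ...) {
  cat(sprintf("Synthetic cohort: %d participants, %d weekly records (t = 0..%d)\n",
              nrow(x$baseline), nrow(x$weekly), x$config$n_followups))
  invisible(x)
}

## Effective symptom weights per RF after mediation overrides. Returns, per
## RF, the weights applied to z(between), z(within at t), z(within at t-1),
## and the marginal (single-RF-model) between/within weights that account for
## the x-m correlation induced by a mediation spec.
effective_effects <- function(config) {
  med <- config$mediation
  out <- lapply(config$rf_specs, function(s)
    list(between = s$effect_between, within = s$effect_within,
         lagged = s$effect_lagged,
         marg_between = s$effect_between, marg_within = s$effect_within))
  if (!is.null(med)) {
    if (med$level == "between") {
      out[[med$m]]$between <- med$b
      out[[med$x]]$between <- med$c_prime
      out[[med$m]]$marg_between <- med$b + med$a * med$c_prime
      out[[med$x]]$marg_between <- med$c_prime + med$a * med$b
    } else {
      out[[med$m]]$within <- med$b
      out[[med$x]]$within <- med$c_prime
      out[[med$m]]$marg_within <- med$b + med$a * med$c_prime
      out[[med$x]]$marg_within <- med$c_prime + med$a * med$b
    }
  }
  out
}

## Stationary AR(1) correlation matrix over occasions t = -1..Tf.
ar1_cor <- function(Tf, rho) {
  idx <- seq_len(Tf + 2L)
  rho^abs(outer(idx, idx, "-"))
}

## Population limit of the within/between mixed-model coefficients for one
## RF channel, accounting for sample-person-mean demeaning (which induces an
## O(1/T) coupling between the demeaned predictor and neighbouring weeks).
## Computed as the pooled least-squares limit over the regressors
## (demeaned, person mean) with moments taken from the AR(1) covariance.
wb_plim <- function(s, e, Tf, sd_sr, lag = 0L) {
  v <- s$within_sd^2
  if (v == 0) return(list(within = NA_real_, between = NA_real_))
  N <- Tf + 1L
  occ <- -1:Tf
  K <- length(occ)
  Cw <- v * s$ar1^abs(outer(occ, occ, "-"))
  sigma2 <- s$between_sd^2 + v
  sigma <- sqrt(sigma2)
  bvec <- rep(0, K); bvec[occ >= 0] <- 1 / N     # person-mean functional
  unit <- function(t) {
    z <- rep(0, K)
    i <- match(t, occ)
    if (!is.na(i)) z[i] <- 1
    z
  }
  pred_occ <- if (lag == 0L) 0:Tf else 0:(Tf - lag)
  A11 <- A12 <- c1 <- c2 <- 0
  for (tt in pred_occ) {
    a <- unit(tt) - bvec
    yw <- (e$within / s$within_sd) * unit(tt + lag) +
      (e$lagged / s$within_sd) * unit(tt + lag - 1L)
    A11 <- A11 + drop(a %*% Cw %*% a)
    A12 <- A12 + drop(a %*% Cw %*% bvec)
    c1 <- c1 + drop(a %*% Cw %*% yw)
    c2 <- c2 + drop(bvec %*% Cw %*% yw)
  }
  np <- length(pred_occ)
  A <- matrix(c(A11 / np / sigma2, A12 / np / sigma2,
                A12 / np / sigma2,
                (s$between_sd^2 + drop(bvec %*% Cw %*% bvec)) / sigma2), 2)
  cc <- c(c1 / np / sigma,
          c2 / np / sigma + e$between * s$between_sd / sigma)
  sol <- solve(A, cc)
  list(within = sol[1] / sd_sr, between = sol[2] / sd_sr)
}

#' Analytic ground truth for a generator configuration
#'
#' Computes, from the generating model alone, the population values of the
#' quantities the downstream estimators target: the normative line, the SD of
#' the true SR score (per week, at baseline, and of the follow-up mean), per-RF
#' intraclass correlations, and the true standardized estimands of the
#' cross-sectional (style -> baseline SR), prospective (style -> mean
#' follow-up SR), contemporaneous within/between, and lagged within models,
#' plus the mediation paths. Estimands are exact for the single-effect
#' configurations used in recovery studies (at most one of
#' \code{effect_within} / \code{effect_lagged} nonzero per RF, no
#' exposure-driven RF dynamics); with several simultaneous within-person
#' effects of the same RF they are first-order approximations.
#'
#' @param config a \code{\link{sim_config}}.
#' @return A list of class \code{"ground_truth"}.
#' @export
ground_truth <- function(config) {
  rfs <- config$rf_specs
  eff <- effective_effects(config)
  med <- config$mediation
  Tf <- config$n_followups
  em <- e_moments(config)
  EE1 <- em$mean
  EE2 <- em$var + em$mean^2

  ## variance of g at one occasion
  var_g <- 0
  for (k in names(rfs)) {
    e <- eff[[k]]
    s <- rfs[[k]]
    var_g <- var_g + e$between^2 + e$within^2 + e$lagged^2 +
      2 * e$within * e$lagged * s$ar1
  }
  if (!is.null(med)) {
    ## add the covariance term between the x and m channels (corr a)
    if (med$level == "between")
      var_g <- var_g + 2 * med$a * med$b * med$c_prime
    else
      var_g <- var_g + 2 * med$a * med$b * med$c_prime
  }
  var_diag <- config$diagnosis_prevalence * (1 - config$diagnosis_prevalence) *
    config$diagnosis_sr_shift^2
  re_var_week <- config$sd_random_intercept^2 +
    config$sd_random_slope^2 * EE2 +
    2 * config$re_correlation * config$sd_random_intercept *
      config$sd_random_slope * EE1
  var_sr_week <- re_var_week + var_g + var_diag + config$residual_sd^2
  sd_sr_week <- sqrt(var_sr_week)
  sd_sr_baseline <- sd_sr_week

  ## variance of the follow-up mean of SR (t = 1..Tf, no dropout)
  EEbar2 <- em$mean^2 + em$var / Tf
  re_var_mean <- config$sd_random_intercept^2 +
    config$sd_random_slope^2 * EEbar2 +
    2 * config$re_correlation * config$sd_random_intercept *
      config$sd_random_slope * EE1
  wsel <- function(t) t + 2L  # column of occasion t in the -1..Tf layout
  var_gbar <- 0
  for (k in names(rfs)) {
    e <- eff[[k]]
    s <- rfs[[k]]
    C <- ar1_cor(Tf, s$ar1)
    a_now <- rep(0, Tf + 2L); a_now[wsel(1:Tf)] <- e$within / Tf
    a_lag <- rep(0, Tf + 2L); a_lag[wsel(0:(Tf - 1L))] <- e$lagged / Tf
    a <- a_now + a_lag
    var_gbar <- var_gbar + e$between^2 + drop(t(a) %*% C %*% a)
  }
  if (!is.null(med) && med$level == "between")
    var_gbar <- var_gbar + 2 * med$a * med$b * med$c_prime
  if (!is.null(med) && med$level == "within") {
    Cx <- ar1_cor(Tf, rfs[[med$x]]$ar1)
    a <- rep(0, Tf + 2L); a[wsel(1:Tf)] <- 1 / Tf
    var_gbar <- var_gbar + 2 * med$a * med$b * med$c_prime *
      drop(t(a) %*% Cx %*% a)
  }
  sd_sr_mean <- sqrt(re_var_mean + var_gbar + var_diag +
                       config$residual_sd^2 / Tf)

  ## per-RF estimands
  per_rf <- lapply(names(rfs), function(k) {
    s <- rfs[[k]]
    e <- eff[[k]]
    sigma_tot <- sqrt(s$between_sd^2 + s$within_sd^2)
    sd_style <- sqrt(s$between_sd^2 + s$style_noise_sd^2)
    rel <- if (sd_style > 0) s$between_sd / sd_style else 0
    ## Var of the person mean of the fluctuation over occasions 0..Tf
    C <- ar1_cor(Tf, s$ar1)
    a <- rep(1 / (Tf + 1L), Tf + 2L); a[1L] <- 0
    var_wbar <- s$within_sd^2 * drop(t(a) %*% C %*% a)
    icc <- if (sigma_tot > 0) s$between_sd^2 / sigma_tot^2 else NA_real_
    ## what a random-intercept-only decomposition converges to: AR(1) serial
    ## correlation shifts part of the within variance into the intercept
    N <- Tf + 1L
    lags <- seq_len(N - 1L)
    avg_corr <- sum(2 * (N - lags) * s$ar1^lags) / (N * (N - 1L))
    vb_eff <- s$between_sd^2 + s$within_sd^2 * avg_corr
    vw_eff <- s$within_sd^2 * (1 - avg_corr)
    icc_estimand <- if (vb_eff + vw_eff > 0) vb_eff / (vb_eff + vw_eff)
      else NA_real_
    h1 <- e$marg_between * rel / sd_sr_baseline
    h2 <- e$marg_between * rel / sd_sr_mean
    e_marg <- list(between = e$marg_between, within = e$marg_within,
                   lagged = e$lagged)
    contemp <- wb_plim(s, e_marg, Tf, sd_sr_week, lag = 0L)
    lagged <- wb_plim(s, e_marg, Tf, sd_sr_week, lag = 1L)
    h3_within <- contemp$within
    h3_between <- contemp$between
    h4_lagged <- lagged$within
    list(name = k, icc = icc, icc_estimand = icc_estimand, h1 = h1, h2 = h2,
         h3_within = h3_within, h3_between = h3_between,
         h4_lagged = h4_lagged)
  })
  names(per_rf) <- names(rfs)

  truth_med <- NULL
  if (!is.null(med)) {
    sx <- rfs[[med$x]]; sm <- rfs[[med$m]]
    if (med$level == "between") {
      a_std <- med$a  # exact when style noise is 0
      b_std <- med$b / sd_sr_baseline
      c_std <- (med$c_prime + med$a * med$b) / sd_sr_baseline
      cprime_std <- med$c_prime / sd_sr_baseline
      b_std_h2 <- med$b / sd_sr_mean
      truth_med <- list(level = "between", a = a_std, b = b_std,
                        c = c_std, c_prime = cprime_std,
                        indirect = a_std * b_std,
                        b_mean_outcome = b_std_h2,
                        indirect_mean_outcome = a_std * b_std_h2)
    } else {
      sig_x <- sqrt(sx$between_sd^2 + sx$within_sd^2)
      sig_m <- sqrt(sm$between_sd^2 + sm$within_sd^2)
      a_w <- med$a * (sm$within_sd / sx$within_sd) * (sig_x / sig_m)
      b_w <- med$b * (sig_m / sm$within_sd) / sd_sr_week
      cprime_w <- med$c_prime * (sig_x / sx$within_sd) / sd_sr_week
      truth_med <- list(level = "within", a = a_w, b = b_w,
                        c = cprime_w + a_w * b_w, c_prime = cprime_w,
                        indirect = a_w * b_w)
    }
  }

  structure(list(
    line = c(intercept = config$ep_intercept, slope = config$ep_slope),
    e_mean = em$mean, e_sd = sqrt(em$var),
    sd_sr_week = sd_sr_week, sd_sr_baseline = sd_sr_baseline,
    sd_sr_mean_followup = sd_sr_mean,
    rf = per_rf, mediation = truth_med), class = "ground_truth")
}

#' Write a cohort to disk as plain-text files
#'
#' Writes \code{baseline.csv} and \code{weekly.csv} (UTF-8, header row,
#' ISO-8601 dates, missing values as empty fields) plus \code{truth.json}.
#'
#' @param cohort a \code{"synth_cohort"} object.
#' @param dir output directory (created if needed).
#' @return Invisibly, the paths written.
#' @export
write_cohort <- function(cohort, dir) {
  if (!inherits(cohort, "synth_cohort"))
    stopf("'cohort' must come from simulate_cohort()")
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  paths <- c(baseline = file.path(dir, "baseline.csv"),
             weekly = file.path(dir, "weekly.csv"),
             truth = file.path(dir, "truth.json"))
  write.csv(cohort$baseline, paths[["baseline"]], row.names = FALSE, na = "")
  write.csv(cohort$weekly, paths[["weekly"]], row.names = FALSE, na = "")
  jsonlite::write_json(unclass(cohort$truth), paths[["truth"]],
                       auto_unbox = TRUE, digits = NA, na = "null")
  invisible(paths)
}
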