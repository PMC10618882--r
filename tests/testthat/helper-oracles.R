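## Independent numerical oracles and scenario builders shared across tests.

## Chi-square(df = 2) upper-tail quantile by numerical integration of the
## density + root finding (independent of qchisq).
chisq2_quantile_oracle <- function(upper_tail) {
  dens <- function(x) 0.5 * exp(-x / 2)  # chi-square density, df = 2
  f <- function(q) integrate(dens, q, Inf, rel.tol = 1e-12)$value - upper_tail
  uniroot(f, c(1, 60), tol = 1e-10)$root
}

## Brute-force distribution-of-the-product quantiles (plain draws, no reuse
## of the package's code path).
product_ci_oracle <- function(a, se_a, b, se_b, level = 0.95, draws = 1e7) {
  z <- rnorm(draws, a, se_a) * rnorm(draws, b, se_b)
  alpha <- (1 - level) / 2
  unname(quantile(z, c(alpha, 1 - alpha)))
}

## ANOVA-based one-way variance-components ICC (oracle independent of lme4):
## ICC(1) = (MSB - MSW) / (MSB + (k - 1) MSW) for balanced groups of size k.
icc_anova_oracle <- function(value, id) {
  k <- mean(table(id))
  fit <- aov(value ~ factor(id))
  ms <- summary(fit)[[1]][["Mean Sq"]]
  (ms[1] - ms[2]) / (ms[1] + (k - 1) * ms[2])
}

## Single-RF scenario config used by the recovery and coverage studies:
## one RF ("X", measured at baseline and weekly), no mediation, no dropout,
## no jitter, no diagnosis shift, so that the analytic ground truth is exact.
scenario_config <- function(n = 200, followups = 5,
                            effect_between = 0, effect_within = 0,
                            effect_lagged = 0, e_effect_within = 0,
                            between_sd = 0.87, within_sd = 0.5, ar1 = 0.3,
                            residual_sd = 1, sd_random_intercept = 0.5,
                            dropout = 0, jitter = 0) {
  sim_config(
    n_participants = n, n_followups = followups,
    rf_specs = list(rf_spec("X", baseline = TRUE, weekly = TRUE,
                            between_sd = between_sd, within_sd = within_sd,
                            ar1 = ar1, effect_between = effect_between,
                            effect_within = effect_within,
                            effect_lagged = effect_lagged,
                            e_effect_within = e_effect_within)),
    mediation = NULL,
    sd_random_intercept = sd_random_intercept, sd_random_slope = 0,
    residual_sd = residual_sd, dropout_prob_per_week = dropout,
    date_jitter_days = jitter, diagnosis_prevalence = 0,
    diagnosis_sr_shift = 0)
}

## Invert the analytic ground truth: the raw effect whose standardized
## estimand equals `target` for the given truth field.
raw_effect_for <- function(target, field, builder) {
  uniroot(function(e) {
    cfg <- builder(e)
    ground_truth(cfg)$rf$X[[field]] - target
  }, c(-5, 5), tol = 1e-10)$root
}

## Weekly SR scores for a cohort via the longitudinal mixed-model line.
weekly_sr <- function(cohort, gate = NULL) {
  w <- cohort$weekly
  fit <- sr_fit(P ~ E, w, id = "id", method = "mixed", outlier_p = gate)
  w$sr <- fit$data$sr
  w
}

## Baseline data with cross-sectional (OLS-line) SR and styles merged on.
baseline_sr <- function(cohort, gate = NULL) {
  bw <- merge(cohort$weekly[cohort$weekly$t == 0,
                            c("id", "E", "P"), drop = FALSE],
              cohort$baseline, by = "id")
  fit <- sr_fit(P ~ E, bw, method = "ols", outlier_p = gate)
  bw$sr <- fit$data$sr
  bw
}
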