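test_that("identical config and seed reproduce byte-identical tables", {
  cfg <- sim_config(n_participants = 60, n_followups = 3)
  a <- simulate_cohort(cfg, seed = 123)
  b <- simulate_cohort(cfg, seed = 123)
  expect_identical(a$baseline, b$baseline)
  expect_identical(a$weekly, b$weekly)
  c <- simulate_cohort(cfg, seed = 124)
  expect_false(identical(a$weekly$P, c$weekly$P))
})

test_that("noise-free degenerate cohort lies exactly on the normative line", {
  cfg <- sim_config(
    n_participants = 40, n_followups = 3,
    rf_specs = list(rf_spec("X", weekly = TRUE)), mediation = NULL,
    sd_random_intercept = 0, sd_random_slope = 0, residual_sd = 0,
    dropout_prob_per_week = 0, date_jitter_days = 0,
    diagnosis_prevalence = 0, diagnosis_sr_shift = 0)
  co <- simulate_cohort(cfg, seed = 5)
  expect_equal(co$weekly$P, 8 + 0.08 * co$weekly$E, tolerance = 1e-12)
  ## downstream SR is identically zero
  scored <- compute_sr(structure(list(intercept = 8, slope = 0.08),
                                 class = "normative_line"), co$weekly)
  expect_true(all(abs(scored$sr) < 1e-10))
  ## every participant-week present, dates exactly weekly
  expect_equal(nrow(co$weekly), 40 * 4)
  gaps <- with(co$weekly[co$weekly$id == co$weekly$id[1], ], diff(date))
  expect_true(all(as.numeric(gaps) == 7))
})

test_that("invalid configuration fields are rejected by name", {
  expect_error(sim_config(n_followups = 0), "n_followups")
  expect_error(sim_config(dropout_prob_per_week = 1.2), "dropout_prob_per_week")
  expect_error(sim_config(residual_sd = -1), "residual_sd")
  expect_error(sim_config(severity_probs = c(1, 1, 1, 1, 1)), "severity_probs")
  expect_error(
    sim_config(rf_specs = list(rf_spec("A"), rf_spec("A"))), "duplicate")
  expect_error(rf_spec("X", ar1 = 1.5), "ar1")
  expect_error(mediation_spec(a = 2), "'a'")
})

test_that("generated RF variance components match the ICC targets", {
  ## serially uncorrelated fluctuations: ICC estimand equals the variance
  ## ratio 0.9^2 / (0.9^2 + 0.5^2) = 0.764
  cfg <- scenario_config(n = 500, between_sd = 0.9, within_sd = 0.5, ar1 = 0)
  co <- simulate_cohort(cfg, seed = 31)
  ora <- icc_anova_oracle(co$weekly$X_mode, co$weekly$id)
  expect_equal(ora, 0.9^2 / (0.9^2 + 0.5^2), tolerance = 0.05)
  fit <- icc(co$weekly, "X_mode")
  expect_equal(fit$icc, ora, tolerance = 0.02)

  ## with AR(1) fluctuations the random-intercept decomposition converges to
  ## the serial-correlation-adjusted estimand carried in the ground truth
  cfg2 <- scenario_config(n = 500, ar1 = 0.5)
  co2 <- simulate_cohort(cfg2, seed = 32)
  fit2 <- icc(co2$weekly, "X_mode")
  expect_equal(fit2$icc, co2$truth$rf$X$icc_estimand, tolerance = 0.04)
  expect_gt(co2$truth$rf$X$icc_estimand, co2$truth$rf$X$icc)
})

test_that("dropout thins completions at the configured binomial rate", {
  cfg <- sim_config(n_participants = 1000, n_followups = 5,
                    rf_specs = list(rf_spec("X")), mediation = NULL,
                    dropout_prob_per_week = 0.1, date_jitter_days = 0,
                    diagnosis_prevalence = 0)
  co <- simulate_cohort(cfg, seed = 77)
  n_fu <- table(factor(co$weekly$id[co$weekly$t > 0],
                       levels = co$baseline$id))
  frac_all5 <- mean(n_fu == 5)
  p <- 0.9^5
  se <- sqrt(p * (1 - p) / 1000)
  expect_lt(abs(frac_all5 - p), 3 * se)
})

test_that("stressor severity draws follow the configured mixture", {
  expect_true(all(draw_stressor_severities(20, 10, occurrence_prob = 0) == 0))
  allfive <- draw_stressor_severities(20, 10, occurrence_prob = 1,
                                      severity_probs = c(0, 0, 0, 0, 1))
  expect_true(all(rowSums(allfive) == 50))
  ## mean exposure within 3 SE of the closed-form mixture mean
  set.seed(99)
  n <- 1e4
  sv <- draw_stressor_severities(n, 40)
  E <- rowSums(sv)
  cfg <- sim_config(n_participants = 10)
  em <- stressreact:::e_moments(cfg)
  expect_lt(abs(mean(E) - em$mean), 3 * sqrt(em$var / n))
  expect_true(all(sv %in% 0:5))
})

test_that("cohort tables round-trip through CSV/JSON on disk", {
  cfg <- sim_config(n_participants = 25, n_followups = 3,
                    rf_specs = list(rf_spec("PA", weekly = TRUE),
                                    rf_spec("PSS", weekly = TRUE)))
  co <- simulate_cohort(cfg, seed = 9)
  dir <- tempfile("cohort")
  paths <- write_cohort(co, dir)
  expect_true(all(file.exists(paths)))
  panel <- load_panel(paths[["baseline"]], paths[["weekly"]])
  expect_equal(nrow(panel$weekly), nrow(co$weekly))
  expect_equal(panel$weekly$E, co$weekly$E)
  expect_equal(panel$weekly$P, co$weekly$P, tolerance = 1e-12)
  expect_equal(panel$weekly$date, co$weekly$date)
  expect_equal(nrow(panel$report), 0L)
  unlink(dir, recursive = TRUE)
})
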