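test_that("person-mean centering is an exact decomposition", {
  d <- data.frame(id = c("a", "a", "a", "b", "b"),
                  t = c(1, 2, 3, 1, 2),
                  v = c(1, 2, 3, 5, 5))
  out <- person_center(d, "v")
  expect_equal(out$v_pm, c(2, 2, 2, 5, 5))
  expect_equal(out$v_dm, c(-1, 0, 1, 0, 0))
  expect_equal(out$v_pm + out$v_dm, d$v)
  ## demeaned values sum to zero within every participant
  set.seed(30)
  big <- data.frame(id = rep(1:40, each = 5), v = rnorm(200))
  bo <- person_center(big, "v")
  sums <- tapply(bo$v_dm, bo$id, sum)
  expect_true(all(abs(sums) < 1e-10))
})

test_that("lag pairing only crosses consecutive retained weeks", {
  set.seed(31)
  n <- 60
  d <- expand.grid(id = sprintf("p%02d", 1:n), t = c(1, 3, 4, 6, 7))
  d$x <- rnorm(nrow(d)); d$y <- rnorm(nrow(d))
  fit <- fit_lagged_rf_sr(d, "x", outcome = "y")
  ## retained weeks {1, 3, 4, 6, 7}: only (3,4) and (6,7) pair up; the
  ## (1,3) and (4,6) gaps are never bridged
  expect_equal(fit$n_obs, 2L * n)
  ## a panel with no consecutive weeks at all is inestimable
  d2 <- d[d$t %in% c(1, 3, 7), ]
  expect_error(fit_lagged_rf_sr(d2, "x", outcome = "y"), "consecutive")
})

test_that("degenerate predictors are refused with a clear message", {
  d <- data.frame(id = rep(1:30, each = 4), t = rep(1:4, 30))
  d$y <- rnorm(nrow(d))
  d$x <- rep(rnorm(30), each = 4)      # constant within persons
  expect_error(fit_contemporaneous(d, "x", outcome = "y"),
               "within-person variance")
})

test_that("contemporaneous model separates within and between effects", {
  ## pure within-person effect: the within estimate matches the analytic
  ## estimand and the between term carries only its small demeaning artifact
  cfg <- scenario_config(n = 400, effect_within = -0.4)
  co <- simulate_cohort(cfg, seed = 33)
  w <- weekly_sr(co)
  fit <- fit_contemporaneous(w, "X_mode")
  expect_lt(abs(fit$within$beta_std - co$truth$rf$X$h3_within),
            3.3 * fit$within$se)
  expect_lt(abs(fit$between$beta_std - co$truth$rf$X$h3_between),
            3.3 * fit$between$se)
  expect_lt(abs(co$truth$rf$X$h3_between), 0.12)  # artifact, not an effect
  ## pure between-person effect: within estimand is exactly zero
  cfgB <- scenario_config(n = 400, effect_between = -0.5)
  coB <- simulate_cohort(cfgB, seed = 34)
  wB <- weekly_sr(coB)
  fitB <- fit_contemporaneous(wB, "X_mode")
  expect_lt(abs(fitB$between$beta_std - coB$truth$rf$X$h3_between),
            3.3 * fitB$between$se)
  expect_lt(abs(fitB$within$beta_std), 3.3 * fitB$within$se)
  expect_equal(coB$truth$rf$X$h3_within, 0)
})

test_that("lagged and contemporaneous effects are mutually discriminant", {
  cfgL <- scenario_config(n = 400, effect_lagged = -0.4)
  coL <- simulate_cohort(cfgL, seed = 35)
  wL <- weekly_sr(coL)
  lag_fit <- fit_lagged_rf_sr(wL, "X_mode")
  expect_lt(abs(lag_fit$within$beta_std - coL$truth$rf$X$h4_lagged),
            3.3 * lag_fit$within$se)
  ## a contemporaneous-only generator with memoryless RF fluctuations: the
  ## lagged estimate equals the small person-mean demeaning artifact, far
  ## from the magnitude a genuine lagged effect of the same size would give
  cfgC <- scenario_config(n = 400, effect_within = -0.4, ar1 = 0)
  coC <- simulate_cohort(cfgC, seed = 36)
  wC <- weekly_sr(coC)
  lag0 <- fit_lagged_rf_sr(wC, "X_mode")
  artifact <- coC$truth$rf$X$h4_lagged
  expect_lt(abs(lag0$within$beta_std - artifact), 3.3 * lag0$within$se)
  expect_lt(abs(artifact), abs(coC$truth$rf$X$h3_within) / 4)
})

test_that("lagged primary targets are judged at the halved alpha", {
  set.seed(32)
  d <- expand.grid(id = sprintf("p%02d", 1:50), t = 1:4)
  d$x <- rnorm(nrow(d)); d$y <- rnorm(nrow(d))
  fit <- fit_lagged_rf_sr(d, "x", outcome = "y", bonferroni_k = 2)
  expect_equal(fit$alpha_adjusted, 0.025)
  expect_equal(fit$significant, fit$within$p < 0.025)
  ## a p-value between .025 and .05 does not pass the primary threshold
  expect_false(0.03 < fit$alpha_adjusted)
})

test_that("autoregressive adjustment recovers persistence structure", {
  ## SR persistence: the time-t outcome coefficient tracks the within-person
  ## autocorrelation that the lagged RF effect would otherwise absorb
  cfg <- scenario_config(n = 300, effect_within = -0.5, ar1 = 0.6)
  co <- simulate_cohort(cfg, seed = 37)
  w <- weekly_sr(co)
  arf <- fit_autoregressive_followup(w, "X_mode")
  expect_false(is.null(arf$ar))
  expect_true(arf$ar$p < 0.05)       # persistence is picked up
  ## a genuinely incremental lagged effect survives the adjustment
  cfgI <- scenario_config(n = 400, effect_lagged = -0.5)
  coI <- simulate_cohort(cfgI, seed = 38)
  wI <- weekly_sr(coI)
  arI <- fit_autoregressive_followup(wI, "X_mode")
  expect_lt(arI$within$p, 0.001)
  expect_lt(arI$within$beta_std, 0)
})

test_that("ICC hits its analytic limits on degenerate panels", {
  d <- data.frame(id = rep(1:50, each = 4), v = rep(rnorm(50), each = 4))
  r1 <- icc(d, "v")
  expect_gt(r1$icc, 0.999)
  expect_equal(r1$flag, "degenerate")
  set.seed(39)
  d2 <- data.frame(id = rep(1:50, each = 4), v = rnorm(200))
  r0 <- icc(d2, "v")
  expect_lt(r0$icc, 0.15)
  dflat <- data.frame(id = rep(1:10, each = 3), v = rep(1, 30))
  expect_equal(icc(dflat, "v")$flag, "degenerate")
})

test_that("multilevel mediation recovers an exact within-person chain", {
  ## noise-free within chain: the mediator tracks the predictor fluctuation
  ## (a = 0.5, plus its own independent wobble) and y = b * m exactly
  set.seed(40)
  n <- 80; Tn <- 5
  id <- rep(seq_len(n), each = Tn)
  x <- rep(rnorm(n), each = Tn) + rnorm(n * Tn)
  xa <- stats::ave(x, id)
  m <- rep(rnorm(n), each = Tn) + 0.5 * (x - xa) + rnorm(n * Tn, 0, 0.5)
  y <- -0.8 * m
  d <- data.frame(id = id, t = rep(1:Tn, n), x = x, m = m, y = y)
  res <- multilevel_mediation(d, "x", "m", "y", draws = 1e4, seed = 5)
  ## y is an exact multiple of m: the standardized b path is exactly -1 and
  ## the direct path vanishes
  expect_equal(res$b, -1, tolerance = 1e-6)
  expect_equal(res$c_prime, 0, tolerance = 1e-6)
  expect_equal(res$indirect, res$a * res$b, tolerance = 1e-12)
  ## the a path equals the within regression of m on x (person effects
  ## absorbed), on the standardized scale
  expect_equal(res$a, 0.5 * sd(d$x) / sd(d$m), tolerance = 0.05)

  ## generator-based recovery against the analytic ground truth
  rfs <- list(rf_spec("PSS", weekly = TRUE), rf_spec("PA", weekly = TRUE))
  cfg <- sim_config(n_participants = 400, rf_specs = rfs,
                    mediation = mediation_spec("PSS", "PA", a = 0.4,
                                               b = -1, c_prime = -0.4,
                                               level = "within"),
                    sd_random_intercept = 0.5, sd_random_slope = 0,
                    residual_sd = 1, dropout_prob_per_week = 0,
                    date_jitter_days = 0, diagnosis_prevalence = 0)
  co <- simulate_cohort(cfg, seed = 41)
  w <- weekly_sr(co)
  mm <- multilevel_mediation(w, "PSS_mode", "PA_mode", "sr",
                             draws = 1e5, seed = 6)
  tm <- co$truth$mediation
  expect_lt(abs(mm$a - tm$a), 0.08)
  expect_lt(abs(mm$b - tm$b), 0.1)
  expect_lt(abs(mm$indirect - tm$indirect), 0.07)
  ## CI is finite and brackets the point estimate
  expect_true(is.finite(mm$ci_lower) && is.finite(mm$ci_upper))
  expect_true(mm$ci_lower <= mm$indirect && mm$indirect <= mm$ci_upper)
})
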