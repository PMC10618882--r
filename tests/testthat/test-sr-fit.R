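test_that("Mahalanobis gate uses the chi-square df=2 cutoff", {
  ## cutoff equals the .001 upper-tail quantile from a numerical oracle
  expect_equal(mahalanobis_outliers(rnorm(10), rnorm(10))$cutoff,
               chisq2_quantile_oracle(0.001), tolerance = 1e-6)
  expect_equal(qchisq(0.999, 2), 13.8155, tolerance = 1e-4)

  ## symmetric cloud + (0, 0): the pair at the centroid has D^2 = 0 exactly
  a <- sqrt(3 / 32)
  cloudE <- c(rep(c(a, -a, 0, 0), 16), 4, -4, 4, -4)
  cloudP <- c(rep(c(0, 0, a, -a), 16), 4, -4, -4, 4)
  g <- mahalanobis_outliers(c(cloudE, 0), c(cloudP, 0))
  expect_equal(g$d2[length(g$d2)], 0, tolerance = 1e-12)
  expect_true(g$retain[length(g$retain)])

  ## this construction has exact zero mean and identity sample covariance,
  ## so the corner (4, 4) sits at D^2 = 32 > 13.8155 and is excluded
  g2 <- mahalanobis_outliers(cloudE, cloudP)
  expect_equal(g2$d2[65], 32, tolerance = 1e-10)
  expect_false(g2$retain[65])
  expect_true(all(g2$retain[1:64]))

  expect_error(mahalanobis_outliers(1:10, 2 * (1:10)), "singular")
  expect_error(mahalanobis_outliers(1:2, 1:2), "at least 3")
})

test_that("OLS normative line matches closed-form least squares", {
  ## perfectly collinear points recover the line exactly
  d <- data.frame(E = c(0, 10, 20, 30, 40), P = 2 + 0.1 * c(0, 10, 20, 30, 40))
  fit <- sr_fit(P ~ E, d, method = "ols", outlier_p = NULL)
  expect_equal(unname(coef(fit)), c(2, 0.1), tolerance = 1e-12)
  expect_true(all(abs(residuals(fit)) < 1e-10))

  ## 5-point toy set against the normal equations
  d2 <- data.frame(E = c(1, 3, 4, 7, 9), P = c(2.2, 2.9, 4.1, 5.0, 7.3))
  b1 <- cov(d2$E, d2$P) / var(d2$E)
  b0 <- mean(d2$P) - b1 * mean(d2$E)
  fit2 <- sr_fit(P ~ E, d2, method = "ols", outlier_p = NULL)
  expect_equal(unname(coef(fit2)), c(b0, b1), tolerance = 1e-10)

  ## shift equivariance: P + c moves the intercept only, SR is unchanged
  d3 <- d2; d3$P <- d3$P + 5
  fit3 <- sr_fit(P ~ E, d3, method = "ols", outlier_p = NULL)
  expect_equal(fit3$line$intercept, fit2$line$intercept + 5, tolerance = 1e-10)
  expect_equal(fit3$line$slope, fit2$line$slope, tolerance = 1e-10)
  expect_equal(residuals(fit3), residuals(fit2), tolerance = 1e-10)

  expect_error(sr_fit(P ~ E, data.frame(E = rep(1, 5), P = 1:5),
                      method = "ols", outlier_p = NULL), "variance")
})

test_that("SR residuals are centered and exposure-orthogonal under OLS", {
  co <- simulate_cohort(sim_config(n_participants = 300,
                                   rf_specs = list(rf_spec("X"))), seed = 21)
  bw <- baseline_sr(co, gate = 0.001)
  sr <- bw$sr[!is.na(bw$sr)]
  E <- bw$E[!is.na(bw$sr)]
  expect_lt(abs(mean(sr)), 1e-10)
  expect_lt(abs(cor(sr, E)), 1e-10)
})

test_that("SR arithmetic follows the line equation and propagates NA", {
  line <- structure(list(intercept = 2, slope = 0.1), class = "normative_line")
  d <- compute_sr(line, data.frame(E = c(10, 30, NA), P = c(5, 5, 5)))
  expect_equal(d$sr, c(5 - 3, 5 - 5, NA))
  ## observation exactly on the line
  expect_equal(compute_sr(line, data.frame(E = 20, P = 4))$sr, 0)
})

test_that("mixed-model line reduces to OLS for degenerate random effects", {
  cfg <- sim_config(n_participants = 80, n_followups = 4,
                    rf_specs = list(rf_spec("X")), mediation = NULL,
                    sd_random_intercept = 0, sd_random_slope = 0,
                    residual_sd = 0.5, dropout_prob_per_week = 0,
                    diagnosis_prevalence = 0)
  co <- simulate_cohort(cfg, seed = 41)
  mixed <- sr_fit(P ~ E, co$weekly, id = "id", method = "mixed",
                  outlier_p = NULL)
  ols <- sr_fit(P ~ E, co$weekly, method = "ols", outlier_p = NULL)
  expect_equal(coef(mixed), coef(ols), tolerance = 1e-3)
  ## noise-free: fixed effects equal the generating line to solver tolerance
  cfg0 <- sim_config(n_participants = 40, n_followups = 3,
                     rf_specs = list(rf_spec("X")), mediation = NULL,
                     sd_random_intercept = 0, sd_random_slope = 0,
                     residual_sd = 1e-4, dropout_prob_per_week = 0,
                     diagnosis_prevalence = 0)
  co0 <- simulate_cohort(cfg0, seed = 42)
  f0 <- sr_fit(P ~ E, co0$weekly, id = "id", method = "mixed",
               outlier_p = NULL)
  expect_equal(unname(coef(f0)), c(8, 0.08), tolerance = 1e-3)

  ## one observation per participant: mixed estimates agree with OLS
  one <- co$weekly[co$weekly$t == 0, ]
  m1 <- suppressWarnings(sr_fit(P ~ E, one, id = "id", method = "mixed",
                                outlier_p = NULL))
  o1 <- sr_fit(P ~ E, one, method = "ols", outlier_p = NULL)
  expect_equal(unname(coef(m1)), unname(coef(o1)), tolerance = 1e-3)
})

test_that("average SR pools retained follow-ups, excluding baseline", {
  d <- data.frame(id = c("a", "a", "a", "a", "a", "b", "c", "c"),
                  t = c(0, 1, 2, 3, 4, 1, 0, 2),
                  sr = c(99, 1, -1, 0, 0, 0.7, 5, NA))
  out <- average_sr(d)
  expect_equal(out$mean_sr[out$id == "a"], 0)       # (1 - 1 + 0 + 0) / 4
  expect_equal(out$mean_sr[out$id == "b"], 0.7)     # single follow-up
  expect_true(is.na(out$mean_sr[out$id == "c"]))    # no usable follow-up
  expect_equal(out$n_followups[out$id == "a"], 4L)
  ## constant SR averages to itself
  cd <- data.frame(id = "z", t = 1:5, sr = rep(0.3, 5))
  expect_equal(average_sr(cd)$mean_sr, 0.3)
})

test_that("quadratic-term check flags curvature and only curvature", {
  set.seed(7)
  E <- runif(500, 0, 40)
  lin <- data.frame(E = E, P = 2 + 0.1 * E + rnorm(500))
  quad <- data.frame(E = E, P = 2 + 0.1 * E + 0.01 * E^2 + rnorm(500))
  expect_lt(test_polynomial_term(quad, "ols")$p, 1e-3)
  ## under a purely linear model the test rejects at about its alpha level
  set.seed(8)
  rej <- mean(replicate(200, {
    E <- runif(120, 0, 40)
    d <- data.frame(E = E, P = 2 + 0.1 * E + rnorm(120))
    test_polynomial_term(d, "ols")$p < 0.05
  }))
  expect_lt(abs(rej - 0.05), 3 * sqrt(0.05 * 0.95 / 200) + 0.01)
  ## longitudinal variant detects strong curvature via the likelihood ratio
  co <- simulate_cohort(scenario_config(n = 150), seed = 71)
  w <- co$weekly
  lrt_null <- test_polynomial_term(w, "mixed")
  expect_gt(lrt_null$p, 0.001)
  w$P <- w$P + 0.01 * w$E^2
  expect_lt(suppressWarnings(test_polynomial_term(w, "mixed"))$p, 1e-3)
})

test_that("sr_fit methods expose the fitted line coherently", {
  co <- simulate_cohort(sim_config(n_participants = 120,
                                   rf_specs = list(rf_spec("X"))), seed = 61)
  bw <- merge(co$weekly[co$weekly$t == 0, c("id", "E", "P")],
              co$baseline, by = "id")
  fit <- sr_fit(P ~ E, bw, method = "ols")
  expect_s3_class(fit, "sr_fit")
  expect_equal(predict(fit, data.frame(E = 0)), fit$line$intercept)
  expect_equal(fitted(fit) + residuals(fit), bw$P,
               tolerance = 1e-10, ignore_attr = TRUE)
  expect_output(print(fit), "Normative E-P line")
  expect_output(print(summary(fit)), "SR: n =")
})
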