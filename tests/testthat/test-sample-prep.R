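mk_panel <- function(gaps, id = "p1") {
  ## gaps[k] = days between follow-up k and the previous assessment
  dates <- as.Date("2020-04-06") + cumsum(c(0, gaps))
  data.frame(id = id, t = seq_along(dates) - 1L, date = dates,
             stringsAsFactors = FALSE)
}

test_that("follow-up spacing keeps the 5-9 day window inclusively", {
  ## regular weekly schedule: everything retained
  all7 <- filter_followup_spacing(mk_panel(rep(7, 5)))
  expect_equal(nrow(all7$retained), 6L)
  expect_equal(nrow(all7$drop_log), 0L)

  ## boundary gaps 5 and 9 retained; 4 and 10 dropped
  b <- filter_followup_spacing(mk_panel(c(5, 9, 4, 10)))
  expect_equal(b$retained$t, c(0, 1, 2))
  expect_equal(sort(b$drop_log$t), c(3, 4))
  expect_true(all(b$drop_log$reason == "spacing"))

  ## gaps (7, 4, 7): week 2 dropped; week 3 is then 11 days from the last
  ## retained point (week 1) and is dropped as well
  g <- filter_followup_spacing(mk_panel(c(7, 4, 7)))
  expect_equal(g$retained$t, c(0, 1))
  expect_equal(sort(g$drop_log$t), c(2, 3))

  ## missing date and missing baseline reason codes
  p <- mk_panel(rep(7, 3))
  p$date[3] <- NA
  m <- filter_followup_spacing(p)
  expect_equal(m$drop_log$reason[m$drop_log$t == 2], "missing_date")
  ## week 3 is 14 days from the last retained point and drops for spacing
  expect_equal(m$drop_log$reason[m$drop_log$t == 3], "spacing")
  nb <- filter_followup_spacing(mk_panel(rep(7, 2))[-1, ])
  expect_equal(nrow(nb$retained), 0L)
  expect_true(all(nb$drop_log$reason == "no_baseline"))

  ## idempotence: filtering the retained rows changes nothing
  again <- filter_followup_spacing(all7$retained)
  expect_equal(again$retained, all7$retained)
  expect_equal(nrow(again$drop_log), 0L)
})

test_that("longitudinal membership needs baseline plus four follow-ups", {
  w <- rbind(mk_panel(rep(7, 5), "full"),       # 5 follow-ups
             mk_panel(rep(7, 3), "short"),      # 3 follow-ups
             mk_panel(rep(7, 4), "nobase")[-1, ],
             mk_panel(rep(7, 4), "exact4"))     # exactly 4
  ret <- filter_followup_spacing(w)$retained
  comp <- filter_completion(ret, min_followups = 4)
  expect_true(comp$in_longitudinal[comp$id == "full"])
  expect_false(comp$in_longitudinal[comp$id == "short"])
  expect_true(comp$in_longitudinal[comp$id == "exact4"])
  expect_false("nobase" %in% comp$id[comp$in_longitudinal])
})

test_that("likelihood-ratio screen retains real signals and nulls at ~20%", {
  set.seed(10)
  n <- 200
  d <- data.frame(sr = rnorm(n))
  d$self <- d$sr
  d$flat <- 1
  cs <- suppressWarnings(
    screen_covariates(d, candidates = c("self", "flat"), sample_kind = "cross"))
  expect_true(cs$screened$retained[cs$screened$candidate == "self"])
  expect_lt(cs$screened$p[cs$screened$candidate == "self"], 1e-10)
  expect_false(cs$screened$retained[cs$screened$candidate == "flat"])
  expect_equal(cs$screened$statistic[cs$screened$candidate == "flat"], 0)
  expect_warning(
    screen_covariates(d, candidates = "flat", sample_kind = "cross"),
    "constant")
  ## always-included covariates survive regardless of screening
  expect_true(all(c("age", "gender", "language") %in% cs$covariates))

  ## a pure-noise candidate passes the p < .2 gate in about 20% of samples
  set.seed(11)
  hits <- replicate(400, {
    dd <- data.frame(sr = rnorm(80), x = rnorm(80))
    screen_covariates(dd, candidates = "x",
                      sample_kind = "cross")$screened$retained
  })
  expect_lt(abs(mean(hits) - 0.2), 3 * sqrt(0.2 * 0.8 / 400) + 0.02)
})

test_that("longitudinal screen uses the weekly mixed model", {
  co <- simulate_cohort(scenario_config(n = 80), seed = 13)
  w <- weekly_sr(co)
  w <- merge(w, co$baseline[c("id")], by = "id")
  w$noise <- rnorm(nrow(w))
  w$signal <- w$sr + rnorm(nrow(w), 0, 0.2)
  cs <- screen_covariates(w, candidates = c("signal", "noise"),
                          sample_kind = "long")
  expect_true(cs$screened$retained[cs$screened$candidate == "signal"])
  expect_lt(cs$screened$p[cs$screened$candidate == "signal"], 1e-6)
})

test_that("top-tertile subset keeps the upper two-thirds with ties", {
  e <- data.frame(id = letters[1:9], mean_E = 1:9)
  expect_setequal(top_tertile_subset(e), letters[4:9])
  ## all-equal exposures: everyone stays
  e2 <- data.frame(id = letters[1:6], mean_E = rep(3, 6))
  expect_setequal(top_tertile_subset(e2), letters[1:6])
  expect_error(top_tertile_subset(e[1:2, ]), "at least 3")
  ## continuous exposures: about 66% retained
  set.seed(4)
  e3 <- data.frame(id = sprintf("i%03d", 1:558), mean_E = rnorm(558, 35, 9))
  frac <- length(top_tertile_subset(e3)) / 558
  expect_equal(frac, 2 / 3, tolerance = 0.01)
})
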