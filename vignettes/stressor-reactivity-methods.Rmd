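---
title: "Stressor reactivity and resilience factors: models, generator, and numerical choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Stressor reactivity methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
library(stressreact)
```

## The outcome-based resilience model

Resilience is operationalized here as *low stressor reactivity* (SR): the
residual of a person's mental-health-problem score P on the sample's
normative exposure–symptom (E–P) regression line. A person whose symptoms
lie below the line, given their actual exposure, is inferred to be more
resilient than the norm. The construction has three stages:

1. **Outlier gating.** The joint (E, P) distribution is screened with
   squared Mahalanobis distances from the sample centroid; cases beyond the
   chi-square(2) upper 0.001 quantile (13.8155) are excluded from line
   fitting and receive no SR score. The gate protects the line's slope from
   leverage points; it is applied to baseline pairs for the cross-sectional
   line and to all pooled participant-weeks for the longitudinal line (the
   pooled choice is ours — a per-week gate would make exclusions depend on
   week-level sample sizes).
2. **Normative line.** Cross-sectionally the line is ordinary least
   squares. For weekly panels it is the fixed-effect part of
   `P ~ E + (1 + E | id)` — a linear mixed model with correlated
   participant random intercepts and exposure slopes, so the line represents
   the *sample-normative* relation while individual deviations live in the
   random effects. A curvature check (`test_polynomial_term()`) compares the
   linear model against one with E² added: an F test for OLS, a
   likelihood-ratio chi-square with ML refits for the mixed model.
3. **Residualization.** `SR = P − (b0 + b1 E)`, applied per
   participant-week by plugging each week's E and P into the line. Lower SR
   = higher resilience; the sign convention is fixed throughout.

Assumptions worth stating: the E–P relation is linear on the analysed range
(checked, not assumed, via the curvature test); symptom noise is additive
and homoscedastic; the normative line is stable over the observation window
(no time-varying intercepts); outliers are mistakes or qualitatively
different cases rather than the phenomenon of interest.

## Association and mediation stages

* **Covariate screen:** each candidate covariate is tested against an
  intercept-only model by a likelihood-ratio test (linear regression for
  cross-sectional SR, a participant-random-intercept model fitted by ML for
  weekly SR) and retained at p < .2 — deliberately liberal, since the
  screen's job is confounder inclusion, not discovery. Age, gender, and
  survey language are always included.
* **Per-RF regressions (cross-sectional / prospective):** one standardized
  multiple regression per resilience factor, never all RFs jointly, so each
  coefficient is a *marginal* association adjusted only for covariates.
  Outcome and focal predictor are z-scored on the analysis rows; categorical
  covariates stay as dummies.
* **Within/between decomposition:** a weekly variable is split into a
  person mean (between-person component) and the deviation from it
  (within-person component). We z-score the outcome and the *raw* predictor
  on the analysis sample first and decompose afterwards, so both components
  share one scale and their coefficients are comparable. Mixed models carry
  a random intercept and a random slope on the demeaned predictor; lag-1
  models pair only *consecutive* retained assessment indices (a lag is a
  week number difference of exactly 1, not a calendar-day difference —
  the spacing filter has already enforced 5–9-day gaps).
* **Autoregressive follow-up:** a significant lagged association is
  re-estimated with the outcome's time-t measurement added, asking whether
  the lagged effect is incremental over mere persistence.
* **Mediation:** Baron–Kenny path regressions; the indirect effect a·b gets
  a distribution-of-the-product interval (quantiles of the product of two
  independent normals centred at the path estimates). Significance of the
  indirect path is judged by this CI excluding zero, not by the classical
  stepwise gate — the four paths are still reported. The multilevel (1-1-1)
  variant uses demeaned predictors with person means and covariates, random
  intercepts, and *fixed* path slopes; random-slope covariance refinements
  are out of scope. The same covariate set enters all three regressions.

## Sample preparation rules

Follow-ups are retained iff their gap from the previous **retained**
sampling point is 5–9 days inclusive; the baseline anchors the chain. We
read "previous sampling time point" as the previous *retained* one: after a
dropped week, the next week is judged against the last good anchor, which
can cascade — the drop log records every removal with exactly one reason
code (`spacing`, `missing_date`, `no_baseline`). The longitudinal sample
requires a completed baseline plus at least four retained follow-ups.
Sensitivity subsetting keeps participants at or above the lower tertile
boundary of mean exposure (inclusive, ties kept, so the subsample is never
smaller than two-thirds).

## Scoring

* Exposure E is the plain sum of 0–5 severity ratings; a missing item
  invalidates that week's E (no imputation of stressor items).
* P is the GHQ-12 total under 0-1-2-3 Likert scoring (range 0–36). The
  alternative binary 0-0-1-1 scoring exists in the literature; we use the
  Likert sum because severity analyses need its variance, and the scoring
  rule is a single place in the code if a user needs the binary variant.
* RF inventories are scored by declarative `scale_definition()`s: reverse
  coding as `min + max − x`, sum or mean rule, and a missing-data gate — a
  score is computed when at least 80% of items are answered (mean-of-answered
  imputation), else missing.

## The synthetic cohort generator

`simulate_cohort()` emulates the statistical structure of a one-baseline +
weekly-follow-up cohort:

* **Exposure:** ~40 checklist items, each occurring independently
  (default probability 0.35) with severities 1–5 drawn from a declining
  mixture; E is the item sum (default mean 35, SD 9). The study reported no
  usable empirical E distribution, so these are free parameters chosen to
  give a realistic occurrence/severity gradient.
* **Symptoms:** `P = b0 + (b1 + u1_i)E + u0_i + g_it + ε_it` with bivariate
  normal participant deviations and i.i.d. weekly noise. Defaults
  (`b0 = 8`, `b1 = 0.08`, residual SD 4) put P in a plausible GHQ range.
* **Resilience factors:** a stable person component (SD 0.87) plus an AR(1)
  weekly fluctuation (stationary SD 0.5, autocorrelation 0.3), giving a
  default intraclass correlation of 0.75 — inside the 0.64–0.85 band
  reported for weekly RF modes. Baseline "styles" are the person component
  plus optional measurement noise, which is what makes prospective
  style→future-SR effects exist by construction. Effects on SR are
  specified per SD of the stable component (between), of the weekly
  fluctuation (within, same week), or of the previous week's fluctuation
  (lagged). A mediation spec builds a true x→m→SR chain at either level.
* **Design features:** monotone weekly dropout (default 0.2/week, which
  reproduces roughly a third of enrollees completing ≥4 follow-ups), visit
  dates jittered uniformly by ±1 day around the 7-day schedule (±2 days
  were allowed by the spacing rule; the default keeps scheduled visits
  inside the window so the filter is exercised by explicit configurations
  rather than by silent attrition), a diagnosis flag (prevalence 0.33)
  adding a constant SR shift (default 2 symptom units ≈ 0.4 SR SDs), and
  optional exact-sum discretization of P into 12 GHQ items.

**What it does not emulate:** pandemic-phase nonstationarity, country or
language effects on the outcome, informative (SR-dependent) dropout,
item-level RF responses, floor/ceiling effects of real questionnaires, and
baseline windows longer than a week. Passing recovery tests on this
generator therefore demonstrates estimator correctness under the stated
model, not robustness to those real-data complications.

### Ground truth and the demeaning artifact

`ground_truth()` returns the *population value of each estimand as the
package's estimators define it*, not merely the raw generating weights.
Two effects make these differ:

* **Sample-person-mean demeaning.** With T+1 occasions, the demeaned
  predictor `(w_t − w̄)` is mechanically correlated with every other week's
  fluctuation through `w̄`. The within/between estimands are therefore
  computed as the exact pooled-least-squares population limit from the
  AR(1) covariance (`wb_plim`), which reproduces, e.g., the small *nonzero*
  lagged coefficient that a purely contemporaneous generator induces
  (order effect/T). Recovery and coverage suites test against these limits.
* **Serial correlation and the ICC.** A random-intercept-only decomposition
  attributes part of the AR(1) within-person covariance to the intercept,
  so its estimand exceeds `between² / (between² + within²)`; both values
  are reported (`icc`, `icc_estimand`). ICC-recovery scenarios use
  serially uncorrelated fluctuations, where the two coincide.

The same artifact limits the autoregressive follow-up: because the person
mean of exposure includes `E_{t+1}`, which drives the RF contemporaneously,
the adjusted model retains a spurious component of order −γ/(T−1), on top
of the classical dynamic-panel (lagged-DV with person effects) bias. With
short panels and strong exposure drives this artifact is itself detectable.
The persistence-only demonstration scenario therefore uses a longer panel
with high autocorrelation and a modest drive (n = 150, T = 12, ρ = 0.8,
γ = 0.07, weak stable component), where the raw-significant /
adjusted-nonsignificant pattern holds in ~90% of replicates. Users should
treat adjusted lagged coefficients near ±γ/(T−1) with caution.

## Numerical and inferential choices

* Mixed models: REML for reported fits; ML refits for likelihood-ratio
  comparisons. Fixed-effect p-values use the Wald normal approximation
  (adequate at ≥200 participants and identical across software ecosystems);
  CIs are estimate ± 1.96·SE.
* Non-convergence fallback ladder: correlated random effects → uncorrelated
  (`||`) → random intercept only → (for the normative line) OLS; each step
  is recorded in the result and surfaced in `print()`. Singular fits are
  accepted (they are the expected outcome when a generating variance is 0).
* Distribution-of-the-product CI: seeded Monte Carlo, default 10^6 draws,
  type-7 interpolated quantiles. Quantile Monte-Carlo error at mediation-
  scale SEs (0.05–0.2) is ~3×10⁻⁴, far below reporting precision; the
  caller's RNG state is preserved.
* Bonferroni: the two primary lagged positive-appraisal tests share α, so
  the primary threshold is .05/2 = .025; a p in (.025, .05) is reported as
  not passing the primary threshold.
* Diagnosis contrast: Student's pooled-variance t (df = n1 + n2 − 2),
  computable from raw scores or from published group summaries alone; the
  pooled form matches the degrees of freedom convention of the reference
  analyses. Zero pooled variance raises an error rather than ±Inf.
* Tertile boundary: `quantile(x, 1/3)` (type 7) with inclusive ≥ and ties
  kept. Degenerate inputs throughout (constant predictors, singular
  covariances, empty groups, no consecutive weeks) raise errors naming the
  offending quantity instead of returning NaN.

## Validation problem sizes

The test suite validates estimators at reduced but statistically meaningful
scales, chosen to give binomial error bars compatible with the asserted
bands: line-recovery coverage over 200 replicates (n = 200, T = 5); effect
recovery with 95%-CI coverage over 500 replicates per design (injected
standardized effects −0.25 between, −0.3 within, −0.3 lagged, asserted
within 92–98%); global-null rejection over 300–500 replicates (~5% at
α = .05); product-CI endpoints against a 10^7-draw brute-force oracle
(±0.002) and indirect-effect coverage over 1000 simulated mediations; ICC
recovery at targets 0.65/0.75/0.85 (n = 500, ±0.05); and the
persistence-pattern rate over 40 replicates (≥80%). `scripts/acceptance.R`
recomputes the same quantities from scratch at comparable sizes.

## Known limitations

* SR inherits any misspecification of the normative line; only a quadratic
  alternative is tested.
* The Wald/normal inference ignores small-sample df corrections
  (Satterthwaite/Kenward–Roger); at n < 100 participants CIs will be
  slightly narrow.
* The multilevel mediation fixes path slopes; heterogeneous within-person
  paths would bias the indirect CI toward overconfidence.
* Listwise (complete-case) handling everywhere; missingness mechanisms are
  not modelled.
* The autoregressive-adjusted lagged model is only trustworthy away from
  the artifact regime described above.
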