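Package: stressreact
Title: Outcome-Based Resilience Analysis via Stressor-Reactivity Scores
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for outcome-based resilience research with intensive
    longitudinal data. Computes stressor-reactivity (SR) scores as residuals
    of mental-health-problem scores on a normative exposure-symptom regression
    line (cross-sectional ordinary least squares or longitudinal mixed model
    with participant-level random intercepts and slopes), with Mahalanobis
    outlier gating and curvature checks. Provides the surrounding analysis
    pipeline: item scoring for stressor checklists and symptom questionnaires,
    follow-up spacing and completion filters, likelihood-ratio covariate
    screening, per-factor standardized regressions of SR on resilience
    factors, within/between person-mean decompositions for contemporaneous and
    lagged mixed models, intraclass correlations, and mediation with
    distribution-of-the-product confidence intervals. Includes a synthetic
    cohort generator with known ground truth for estimator validation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    lme4,
    jsonlite,
    stats,
    utils,
    graphics
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
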