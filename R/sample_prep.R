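#' Retain follow-ups respecting the 5-9 day spacing rule
#'
#' A follow-up is retained iff its gap from the previous \emph{retained}
#' sampling time point lies in [5, 9] days inclusive; the baseline assessment
#' (\code{t == baseline_t}) is always retained. Rows without a date are
#' dropped. Participants lacking a baseline row have all their follow-ups
#' dropped (\code{no_baseline}).
#'
#' @param weekly long-format data frame with id, assessment-index, and date
#'   columns.
#' @param id,t,date column names.
#' @param min_gap,max_gap inclusive spacing bounds in days.
#' @param baseline_t assessment index of the baseline.
#' @return List with \code{retained} (the surviving rows) and
#'   \code{drop_log} (columns id, t, reason in
#'   \{missing_date, spacing, no_baseline\}).
#' @export
filter_followup_spacing <- function(weekly, id = "id", t = "t", date = "date",
                                    min_gap = 5, max_gap = 9, baseline_t = 0) {
  check_cols(weekly, c(id, t, date), "filter_followup_spacing")
  weekly <- as.data.frame(weekly)
  weekly <- weekly[order(weekly[[id]], weekly[[t]]), , drop = FALSE]
  keep <- logical(nrow(weekly))
  reasons <- character(nrow(weekly))
  for (pid in unique(weekly[[id]])) {
    rows <- which(weekly[[id]] == pid)
    base <- rows[weekly[[t]][rows] == baseline_t]
    if (!length(base)) {
      reasons[rows] <- "no_baseline"
      next
    }
    keep[base] <- TRUE
    last_date <- weekly[[date]][base[1L]]
    for (r in setdiff(rows, base)) {
      d <- weekly[[date]][r]
      if (is.na(d)) { reasons[r] <- "missing_date"; next }
      gap <- as.numeric(difftime(d, last_date, units = "days"))
      if (gap >= min_gap && gap <= max_gap) {
        keep[r] <- TRUE
        last_date <- d
      } else reasons[r] <- "spacing"
    }
  }
  drop_log <- data.frame(id = weekly[[id]][!keep], t = weekly[[t]][!keep],
                         reason = reasons[!keep], stringsAsFactors = FALSE)
  list(retained = weekly[keep, , drop = FALSE], drop_log = drop_log)
}

#' Longitudinal sample membership: completed baseline and enough follow-ups
#'
#' A participant enters the longitudinal sample iff a baseline assessment is
#' present and at least \code{min_followups} follow-ups were retained (after
#' the spacing filter).
#'
#' @param weekly retained weekly rows (see
#'   \code{\link{filter_followup_spacing}}).
#' @param id,t column names.
#' @param min_followups minimum number of retained follow-ups.
#' @param baseline_t assessment index of the baseline.
#' @return Data frame with \code{id}, \code{has_baseline},
#'   \code{n_followups}, \code{in_longitudinal}.
#' @export
filter_completion <- function(weekly, id = "id", t = "t", min_followups = 4,
                              baseline_t = 0) {
  check_cols(weekly, c(id, t), "filter_completion")
  ids <- unique(weekly[[id]])
  has_base <- vapply(ids, function(p)
    any(weekly[[t]][weekly[[id]] == p] == baseline_t), logical(1))
  n_fu <- vapply(ids, function(p)
    sum(weekly[[id]] == p & weekly[[t]] != baseline_t), integer(1))
  data.frame(id = ids, has_baseline = has_base, n_followups = n_fu,
             in_longitudinal = has_base & n_fu >= min_followups,
             stringsAsFactors = FALSE, row.names = NULL)
}

#' Likelihood-ratio covariate screen
#'
#' Screens candidate covariates for inclusion in the SR models: each
#' candidate is tested against the intercept-only model by a likelihood-ratio
#' test and retained when p < \code{threshold} (default .2). Cross-sectional
#' screening uses linear regression of SR on the candidate; longitudinal
#' screening uses a participant-random-intercept mixed model on weekly SR
#' (fitted by ML). Age, gender, and survey language are always included
#' regardless of the screen.
#'
#' @param data analysis rows holding the outcome and candidates.
#' @param outcome outcome column (SR).
#' @param candidates character vector of candidate covariate columns.
#' @param sample_kind \code{"cross"} or \code{"long"}.
#' @param id participant-id column (longitudinal screen).
#' @param threshold LRT retention threshold.
#' @param always covariates included irrespective of the screen.
#' @return An object of class \code{"covariate_set"}: \code{always},
#'   \code{screened} (data frame with statistic, df, p, retained), and
#'   \code{covariates} (the union, for downstream models).
#' @export
screen_covariates <- function(data, outcome = "sr", candidates,
                              sample_kind = c("cross", "long"), id = "id",
                              threshold = 0.2,
                              always = c("age", "gender", "language")) {
  sample_kind <- match.arg(sample_kind)
  check_cols(data, c(outcome, candidates), "screen_covariates")
  if (sample_kind == "long") check_cols(data, id, "screen_covariates (long)")
  rows <- list()
  for (cand in candidates) {
    d <- data[stats::complete.cases(data[[outcome]], data[[cand]]), ,
              drop = FALSE]
    x <- d[[cand]]
    constant <- length(unique(x[!is.na(x)])) < 2L
    if (constant) {
      rows[[cand]] <- data.frame(candidate = cand, statistic = 0,
                                 df = 0, p = 1, retained = FALSE,
                                 stringsAsFactors = FALSE)
      warnf("covariate screen: candidate '%s' is constant; excluded", cand)
      next
    }
    if (sample_kind == "cross") {
      m1 <- stats::lm(stats::as.formula(paste(outcome, "~", cand)), d)
      m0 <- stats::lm(stats::as.formula(paste(outcome, "~ 1")), d)
    } else {
      m1 <- suppressMessages(lme4::lmer(
        stats::as.formula(sprintf("%s ~ %s + (1 | %s)", outcome, cand, id)),
        d, REML = FALSE,
        control = lme4::lmerControl(check.conv.singular = "ignore")))
      m0 <- suppressMessages(lme4::lmer(
        stats::as.formula(sprintf("%s ~ 1 + (1 | %s)", outcome, id)),
        d, REML = FALSE,
        control = lme4::lmerControl(check.conv.singular = "ignore")))
    }
    df <- attr(stats::logLik(m1), "df") - attr(stats::logLik(m0), "df")
    lr <- max(0, 2 * (as.numeric(stats::logLik(m1)) -
                        as.numeric(stats::logLik(m0))))
    p <- stats::pchisq(lr, df = df, lower.tail = FALSE)
    rows[[cand]] <- data.frame(candidate = cand, statistic = lr, df = df,
                               p = p, retained = p < threshold,
                               stringsAsFactors = FALSE)
  }
  screened <- if (length(rows)) do.call(rbind, rows)
    else data.frame(candidate = character(), statistic = numeric(),
                    df = numeric(), p = numeric(), retained = logical())
  rownames(screened) <- NULL
  structure(list(always = always, screened = screened,
                 covariates = c(always, screened$candidate[screened$retained]),
                 threshold = threshold, sample_kind = sample_kind),
            class = "covariate_set")
}

#' @export
print.covariate_set <- function(x, ...) {
  cat(sprintf("Covariate set (%s sample, LRT p < %.2g)\n", x$sample_kind,
              x$threshold))
  cat("  always included:", paste(x$always, collapse = ", "), "\n")
  kept <- x$screened$candidate[x$screened$retained]
  cat("  screened in:   ",
      if (length(kept)) paste(kept, collapse = ", ") else "(none)", "\n")
  invisible(x)
}

#' Restrict to the top two tertiles of mean stressor exposure
#'
#' Retains participants whose mean exposure over the observation period is at
#' or above the sample's lower tertile boundary (ties kept), the sensitivity
#' subsample used to confirm results under a stricter adversity criterion.
#'
#' @param mean_e data frame with participant ids and mean exposure, or a
#'   named numeric vector.
#' @param id,value column names when \code{mean_e} is a data frame.
#' @return Character vector of retained participant ids.
#' @export
top_tertile_subset <- function(mean_e, id = "id", value = "mean_E") {
  if (is.data.frame(mean_e)) {
    check_cols(mean_e, c(id, value), "top_tertile_subset")
    v <- stats::setNames(mean_e[[value]], mean_e[[id]])
  } else v <- mean_e
  v <- v[!is.na(v)]
  if (length(v) < 3L) stopf("need at least 3 participants to form tertiles")
  boundary <- stats::quantile(v, 1 / 3, names = FALSE)
  names(v)[v >= boundary]
}
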