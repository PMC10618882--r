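#' Define a psychometric scale for item scoring
#'
#' @param name scale label.
#' @param items character vector of item column names (unique).
#' @param range numeric length-2 response range \code{c(min, max)}.
#' @param reverse items (subset of \code{items}) recoded as
#'   \code{min + max - x} before aggregation.
#' @param rule \code{"sum"} or \code{"mean"}.
#' @param max_missing maximum fraction of missing items tolerated; above it
#'   the score is \code{NA}. Answered-item mean imputation is used below it
#'   (for \code{rule = "sum"} the mean of answered items is scaled up to the
#'   full item count).
#' @return An object of class \code{"scale_definition"}.
#' @export
scale_definition <- function(name, items, range = c(1, 5),
                             reverse = character(), rule = c("sum", "mean"),
                             max_missing = 0.2) {
  rule <- match.arg(rule)
  if (anyDuplicated(items))
    stopf("scale '%s': item ids must be unique", name)
  if (!all(reverse %in% items))
    stopf("scale '%s': reverse-coded items must be a subset of the items", name)
  if (length(range) != 2L || range[1] >= range[2])
    stopf("scale '%s': 'range' must be c(min, max) with min < max", name)
  check_prob(max_missing, "max_missing")
  structure(list(name = name, items = items, range = range,
                 reverse = reverse, rule = rule, max_missing = max_missing),
            class = "scale_definition")
}

#' Score a scale from item responses
#'
#' Reverse-coded items are mapped to \code{min + max - x}; the score is the
#' sum or mean per the definition. A score is returned as \code{NA} when more
#' than \code{max_missing} of the items are unanswered; otherwise missing
#' items are implicitly imputed by the mean of the answered items.
#'
#' @param responses data frame (or named list) holding the item columns.
#' @param definition a \code{\link{scale_definition}}.
#' @return Numeric vector of scores, one per row.
#' @export
score_scale <- function(responses, definition) {
  if (!inherits(definition, "scale_definition"))
    stopf("'definition' must be a scale_definition")
  responses <- as.data.frame(responses)
  check_cols(responses, definition$items, sprintf("scale '%s'", definition$name))
  x <- as.matrix(responses[definition$items])
  rng <- definition$range
  ok <- is.na(x) | (x >= rng[1] & x <= rng[2])
  if (!all(ok))
    stopf("scale '%s': responses outside [%g, %g]", definition$name,
          rng[1], rng[2])
  rev_idx <- definition$items %in% definition$reverse
  x[, rev_idx] <- rng[1] + rng[2] - x[, rev_idx]
  n_items <- length(definition$items)
  answered <- rowSums(!is.na(x))
  mean_ans <- rowMeans(x, na.rm = TRUE)
  score <- if (definition$rule == "mean") mean_ans else mean_ans * n_items
  score[answered < (1 - definition$max_missing) * n_items] <- NA_real_
  score[answered == 0] <- NA_real_
  score
}

#' Stressor exposure E: summed severity ratings
#'
#' E is the total of all checklist severity ratings (0 = did not happen,
#' 1-5 = increasing burden) in the reporting window. Any missing severity
#' invalidates E for that record.
#'
#' @param severities numeric matrix or data frame of item severities (one row
#'   per record), each entry in 0-5.
#' @return Integer vector of exposures in \code{0 .. 5 * n_items}.
#' @export
score_stressor_exposure <- function(severities) {
  x <- as.matrix(as.data.frame(severities))
  bad <- !is.na(x) & (x < 0 | x > 5 | x != round(x))
  if (any(bad))
    stopf("stressor severities must be integers in 0..5 (%d offending value(s))",
          sum(bad))
  out <- rowSums(x)
  out[rowSums(is.na(x)) > 0] <- NA
  as.integer(out)
}

#' Mental health problems P: GHQ-12 Likert total
#'
#' Sums 12 General Health Questionnaire items scored 0-1-2-3, giving a total
#' in 0-36.
#'
#' @param items numeric matrix or data frame with exactly 12 columns, entries
#'   in 0-3.
#' @return Integer vector of totals in 0-36.
#' @export
score_ghq <- function(items) {
  x <- as.matrix(as.data.frame(items))
  if (ncol(x) != 12L)
    stopf("GHQ-12 scoring needs exactly 12 item columns, got %d", ncol(x))
  bad <- !is.na(x) & (x < 0 | x > 3 | x != round(x))
  if (any(bad))
    stopf("GHQ item codes must be integers in 0..3 (%d offending value(s))",
          sum(bad))
  out <- rowSums(x)
  out[rowSums(is.na(x)) > 0] <- NA
  as.integer(out)
}

#' Load and validate a baseline + weekly panel from CSV
#'
#' Reads the two long-format tables written by \code{\link{write_cohort}} (or
#' equivalently structured files), parses ISO-8601 dates, and validates
#' structural invariants: unique \code{(id, t)} pairs in the weekly table,
#' unique ids at baseline, parseable dates, and integer severities in 0-5 for
#' any \code{stress_*} columns.
#'
#' @param baseline_path,weekly_path CSV file paths.
#' @return List with elements \code{baseline} and \code{weekly}
#'   (data frames) and \code{report}, a data frame of row-level validation
#'   notes (empty when clean).
#' @export
load_panel <- function(baseline_path, weekly_path) {
  for (p in c(baseline_path, weekly_path))
    if (!file.exists(p)) stopf("input file does not exist: %s", p)
  baseline <- read.csv(baseline_path, stringsAsFactors = FALSE)
  weekly <- read.csv(weekly_path, stringsAsFactors = FALSE)
  notes <- list()

  if (nrow(weekly) == 0L) {
    warnf("weekly file '%s' contains no records", weekly_path)
  } else {
    check_cols(weekly, c("id", "t", "date"), "weekly table")
    dup <- duplicated(weekly[c("id", "t")])
    if (any(dup)) {
      pairs <- unique(sprintf("(%s, t=%s)", weekly$id[dup], weekly$t[dup]))
      stopf("duplicate (id, t) pair(s) in weekly table: %s",
            paste(pairs, collapse = ", "))
    }
    d <- as.Date(weekly$date, format = "%Y-%m-%d")
    bad_date <- which(is.na(d) & !is.na(weekly$date) & nzchar(weekly$date))
    if (length(bad_date))
      stopf("unparseable date(s) in weekly table rows: %s",
            paste(utils::head(bad_date, 10), collapse = ", "))
    weekly$date <- d
    sev_cols <- grep("^stress_", names(weekly), value = TRUE)
    if (length(sev_cols)) {
      sv <- as.matrix(weekly[sev_cols])
      bad <- which(!is.na(sv) & (sv < 0 | sv > 5 | sv != round(sv)),
                   arr.ind = TRUE)
      if (nrow(bad))
        stopf("severity values outside 0..5 in weekly rows: %s",
              paste(utils::head(unique(bad[, 1]), 10), collapse = ", "))
    }
    na_date <- which(is.na(weekly$date))
    if (length(na_date))
      notes[[length(notes) + 1L]] <- data.frame(
        table = "weekly", row = na_date, issue = "missing date",
        stringsAsFactors = FALSE)
  }

  if (nrow(baseline)) {
    check_cols(baseline, "id", "baseline table")
    if (anyDuplicated(baseline$id))
      stopf("duplicate participant id(s) in baseline table: %s",
            paste(unique(baseline$id[duplicated(baseline$id)]), collapse = ", "))
    if ("date" %in% names(baseline))
      baseline$date <- as.Date(baseline$date, format = "%Y-%m-%d")
    orphan <- nrow(weekly) > 0L && !all(weekly$id %in% baseline$id)
    if (orphan) {
      ids <- setdiff(unique(weekly$id), baseline$id)
      notes[[length(notes) + 1L]] <- data.frame(
        table = "weekly", row = which(weekly$id %in% ids),
        issue = "id missing from baseline", stringsAsFactors = FALSE)
    }
  }

  report <- if (length(notes)) do.call(rbind, notes)
    else data.frame(table = character(), row = integer(), issue = character(),
                    stringsAsFactors = FALSE)
  list(baseline = baseline, weekly = weekly, report = report)
}
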