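# The 13 temporal fluency metrics computed from an event sequence.

#' Metric column names, in canonical order
#'
#' @return Character vector of the 13 metric names.
#' @export
metric_names <- function() {
  c("speech_rate_wpm", "total_pause_time_s", "pause_count", "mean_pause_ms",
    "mean_vocal_ms", "pause_cv", "vocal_cv", "mean_long_pause_ms",
    "mean_short_pause_ms", "long_pause_cv", "short_pause_cv",
    "long_pause_count", "short_pause_count")
}

cv_of <- function(x) {
  if (length(x) < 2) return(NA_real_)
  sd(x) / mean(x)
}
mean_or_na <- function(x) if (length(x) == 0) NA_real_ else mean(x)

#' Compute the temporal fluency metrics for one recording
#'
#' Thirteen metrics: speech rate (passage words per minute of recording
#' time), total pause time, pause count, mean pause and vocal durations,
#' their coefficients of variation, and the same count/mean/CV statistics
#' split by short and long pauses. Coefficients of variation use the sample
#' standard deviation (n - 1); statistics of an empty or singleton event
#' subset are reported as `NA`, never as zero, so they cannot corrupt group
#' summaries downstream.
#'
#' @param events An `event_sequence` (see [detect_events()]).
#' @param word_count Number of words in the read passage (default 236, the
#'   standard adult reading passage).
#' @param duration_s Trimmed recording duration in seconds; defaults to the
#'   duration recorded on `events`. The speech-rate denominator is this full
#'   duration (vocal plus pause time).
#' @return A `metric_set`: named list of the 13 metrics.
#' @export
compute_metrics <- function(events, word_count = 236, duration_s = NULL) {
  stopifnot(inherits(events, "event_sequence"))
  if (is.null(duration_s)) duration_s <- attr(events, "signal_duration_s")
  if (!is.numeric(word_count) || word_count < 1)
    stopf("word_count must be a positive count")
  if (!is.numeric(duration_s) || duration_s <= 0)
    stopf("duration_s must be positive")

  p <- events$duration_ms[events$kind == "pause"]
  v <- events$duration_ms[events$kind == "vocal"]
  pl <- events$duration_ms[events$kind == "pause" & events$subtype == "long"]
  ps <- events$duration_ms[events$kind == "pause" & events$subtype == "short"]

  out <- list(
    speech_rate_wpm = word_count / (duration_s / 60),
    total_pause_time_s = sum(p) / 1000,
    pause_count = length(p),
    mean_pause_ms = mean_or_na(p),
    mean_vocal_ms = mean_or_na(v),
    pause_cv = cv_of(p),
    vocal_cv = cv_of(v),
    mean_long_pause_ms = mean_or_na(pl),
    mean_short_pause_ms = mean_or_na(ps),
    long_pause_cv = cv_of(pl),
    short_pause_cv = cv_of(ps),
    long_pause_count = length(pl),
    short_pause_count = length(ps)
  )
  structure(out, class = "metric_set")
}

#' @export
print.metric_set <- function(x, ...) {
  cat("<metric_set>\n")
  for (nm in metric_names())
    cat(sprintf("  %-22s %s\n", nm, format(x[[nm]], digits = 6)))
  invisible(x)
}

#' @export
as.data.frame.metric_set <- function(x, ...) {
  as.data.frame(unclass(x), ...)
}

#' Assemble per-recording metrics and covariates into a cohort table
#'
#' @param metric_sets Named list of `metric_set` objects (names are
#'   participant ids), or a list plus explicit ids in `covariates`.
#' @param covariates Data frame with one row per recording:
#'   `participant_id`, `group` (`"AWS"`/`"AWNS"`), `sex`
#'   (`"male"`/`"female"`), `age`, and optionally `percent_ss` (percent
#'   syllables stuttered; may be missing, e.g. for the non-stuttering
#'   group).
#' @return A `cohort_table` data frame: covariates followed by the 13 metric
#'   columns, one row per recording. Missing metric values propagate as
#'   `NA`.
#' @export
metrics_table <- function(metric_sets, covariates) {
  ids <- covariates$participant_id
  if (is.null(ids)) stopf("covariates must contain participant_id")
  if (anyDuplicated(ids)) stopf("duplicate participant ids")
  if (length(metric_sets) != length(ids))
    stopf("need one metric_set per covariate row")
  if (!is.null(names(metric_sets)) && !all(names(metric_sets) == ids))
    metric_sets <- metric_sets[as.character(ids)]
  m <- do.call(rbind, lapply(metric_sets, function(s)
    as.data.frame(unclass(s))))
  rownames(m) <- NULL
  if (!"percent_ss" %in% names(covariates)) covariates$percent_ss <- NA_real_
  out <- cbind(covariates, m)
  class(out) <- c("cohort_table", "data.frame")
  out
}

#' Validate a cohort table
#'
#' Checks vocabularies and ranges: groups in `{AWS, AWNS}`, sex in
#' `{male, female}`, positive ages, `percent_ss` within `[0, 100]` when
#' present.
#'
#' @param table A `cohort_table` (or plain data frame with its columns).
#' @return The table, invisibly; errors on violation.
#' @export
validate_cohort <- function(table) {
  if (!all(table$group %in% c("AWS", "AWNS")))
    stopf("group must be AWS or AWNS")
  if (!all(table$sex %in% c("male", "female")))
    stopf("sex must be male or female")
  if (any(table$age <= 0, na.rm = TRUE)) stopf("ages must be positive")
  ss <- table$percent_ss
  if (any(ss < 0 | ss > 100, na.rm = TRUE))
    stopf("percent_ss must lie in [0, 100]")
  invisible(table)
}
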