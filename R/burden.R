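# Premature-beat burden: event counting and frequency-based positivity.

#' Positivity criteria for premature-beat burden
#'
#' The clinical rule: a PSVC/PVC frequency of at least 60 events per 2-hour
#' recording, or 720 per 24-hour recording, is called positive. Both encode
#' the same 30 events/hour rate; the constructor asserts that identity.
#'
#' @param threshold_2h positive count threshold for a 2 h window.
#' @param threshold_24h positive count threshold for a 24 h window.
#' @return an object of class `positivity_criteria`.
#' @export
positivity_criteria <- function(threshold_2h = 60L, threshold_24h = 720L) {
  if (threshold_2h < 1 || threshold_24h < 1) {
    stop_config("threshold", "thresholds must be >= 1")
  }
  if (threshold_2h / 2 != threshold_24h / 24) {
    stop_config("threshold_24h",
                "must encode the same events/hour rate as threshold_2h")
  }
  structure(list(threshold_2h = as.integer(threshold_2h),
                 threshold_24h = as.integer(threshold_24h),
                 rate_per_h = threshold_2h / 2),
            class = "positivity_criteria")
}

#' Count labelled events in a beat annotation
#'
#' @param annotation data frame with a `label` column (values in
#'   `c("N", "PSVC", "PVC")`).
#' @param condition `"PSVC"` or `"PVC"`.
#' @param window_h monitoring window length in hours.
#' @param patient_id optional identifier carried through.
#' @return a one-row data frame (a count record): `patient_id`, `condition`,
#'   `count`, `window_h`.
#' @export
count_events <- function(annotation, condition = c("PSVC", "PVC"), window_h,
                         patient_id = NA_character_) {
  condition <- match.arg(condition)
  bad <- setdiff(unique(annotation$label), c("N", "PSVC", "PVC"))
  if (length(bad)) stop("count_events: unknown label(s): ", paste(bad, collapse = ", "))
  if (window_h <= 0) stop_config("window_h", "must be > 0")
  data.frame(patient_id = patient_id, condition = condition,
             count = sum(annotation$label == condition), window_h = window_h,
             stringsAsFactors = FALSE)
}

window_threshold <- function(window_h, criteria) {
  if (window_h == 2) {
    criteria$threshold_2h
  } else if (window_h == 24) {
    criteria$threshold_24h
  } else {
    warning(sprintf("call_positivity: non-standard window %g h; using pro-rata %g/hour rule",
                    window_h, criteria$rate_per_h))
    as.integer(ceiling(criteria$rate_per_h * window_h))
  }
}

#' Call burden positivity from an event count
#'
#' Positive iff `count >= threshold` for the window (boundary inclusive:
#' exactly 60 events in 2 h is positive). Windows other than 2 or 24 h fall
#' back to a pro-rata 30/hour threshold with a warning.
#'
#' @param count non-negative event count (vectorised).
#' @param window_h window length in hours (2 or 24 for the standard rule).
#' @param criteria a [positivity_criteria()].
#' @return character vector, `"positive"` or `"negative"`.
#' @export
call_positivity <- function(count, window_h, criteria = positivity_criteria()) {
  stopifnot(inherits(criteria, "positivity_criteria"))
  if (any(count < 0)) stop("call_positivity: negative count")
  if (window_h <= 0) stop_config("window_h", "must be > 0")
  thr <- window_threshold(window_h, criteria)
  ifelse(count >= thr, "positive", "negative")
}

#' Probability of a positive call under homogeneous Poisson events
#'
#' For a patient with true event rate `rate_per_h`, the count in a window of
#' `window_h` hours is Poisson(rate * window), so
#' `P(positive) = 1 - PoissonCDF(threshold - 1; rate * window)`.
#'
#' @param rate_per_h true event rate in events/hour (vectorised).
#' @param window_h window length in hours.
#' @param criteria a [positivity_criteria()].
#' @return probability in `[0, 1]`.
#' @export
positivity_probability <- function(rate_per_h, window_h, criteria = positivity_criteria()) {
  stopifnot(inherits(criteria, "positivity_criteria"))
  if (any(rate_per_h < 0)) stop_config("rate_per_h", "must be >= 0")
  thr <- window_threshold(window_h, criteria)
  1 - stats::ppois(thr - 1, rate_per_h * window_h)
}
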