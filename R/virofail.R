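## Viral-load monitoring rules and confirmed-virological-failure detection.
##
## Monitoring: a long-acting-arm viral load >= 200 copies/ml prompts a
## repeat test 4-6 weeks later; the oral arm uses a higher trigger of
## >= 1000 copies/ml with a repeat 10-16 weeks later (allowing adherence
## counselling first). Confirmed virological failure (CVF) is two
## consecutive measurements >= 200 copies/ml, in either arm; "consecutive"
## means consecutive measurements in the participant's day-sorted series,
## whatever their spacing. A single >= 200 measurement that could never be
## repeated (e.g. death before retest) can be adjudicated as failure; the
## adjudication is always an explicit input record, never inferred.

#' Arm-specific viral-load monitoring rule
#'
#' @param arm `"long_acting"` or `"oral"`.
#' @return list with `arm`, `trigger_threshold` (copies/ml),
#'   `retest_window_weeks` (lo, hi), `confirm_threshold` (200 copies/ml).
#' @export
monitoring_rule <- function(arm = c("long_acting", "oral")) {
  arm <- match.arg(arm)
  if (arm == "long_acting") {
    list(arm = arm, trigger_threshold = 200,
         retest_window_weeks = c(4L, 6L), confirm_threshold = 200)
  } else {
    list(arm = arm, trigger_threshold = 1000,
         retest_window_weeks = c(10L, 16L), confirm_threshold = 200)
  }
}

#' Retest window triggered by a viral-load result
#'
#' Returns the study-day interval in which a repeat test is due, or `NULL`
#' when the value does not meet the arm's trigger threshold. Censored
#' values (`below_lloq`) never trigger.
#'
#' @param study_day day of the triggering measurement.
#' @param copies_per_ml measured value.
#' @param below_lloq whether the value was censored at the assay limit.
#' @param rule a [monitoring_rule()].
#' @return integer vector `c(start_day, end_day)` or `NULL`.
#' @export
#' @examples
#' retest_due(504, 259, FALSE, monitoring_rule("long_acting"))
retest_due <- function(study_day, copies_per_ml, below_lloq, rule) {
  if (isTRUE(below_lloq)) return(NULL)
  if (is.na(copies_per_ml) || copies_per_ml < rule$trigger_threshold) {
    return(NULL)
  }
  as.integer(study_day + 7L * rule$retest_window_weeks)
}

#' Detect confirmed virological failure in one viral-load series
#'
#' Scans the day-sorted series for the first pair of consecutive
#' measurements both at or above the confirmation threshold; `failure_day`
#' is the day of the first of the pair. When no pair exists but a single
#' measurement meets the threshold and the participant carries an
#' adjudication record for it, the status is `adjudicated_unconfirmed`
#' (counted as failure only where configured).
#'
#' @param viral_loads the participant's viral-load rows.
#' @param rule a [monitoring_rule()].
#' @param adjudicated_day day of an adjudicated unconfirmed failure
#'   (`NA` if none); must match a measurement day at or above the threshold.
#' @return list: `confirmed`, `adjudicated_unconfirmed`, `failure_day`,
#'   `pair_days` (days of the qualifying pair, or `NULL`).
#' @export
detect_cvf <- function(viral_loads, rule, adjudicated_day = NA) {
  no <- list(confirmed = FALSE, adjudicated_unconfirmed = FALSE,
             failure_day = NA_integer_, pair_days = NULL)
  if (is.null(viral_loads) || !nrow(viral_loads)) return(no)
  vl <- viral_loads[order(viral_loads$study_day), , drop = FALSE]
  high <- !vl$below_lloq & !is.na(vl$copies_per_ml) &
    vl$copies_per_ml >= rule$confirm_threshold
  if (length(high) >= 2) {
    pair <- which(high[-length(high)] & high[-1])
    if (length(pair)) {
      i <- pair[[1L]]
      return(list(confirmed = TRUE, adjudicated_unconfirmed = FALSE,
                  failure_day = vl$study_day[[i]],
                  pair_days = vl$study_day[c(i, i + 1L)]))
    }
  }
  if (!is.na(adjudicated_day) && any(high & vl$study_day == adjudicated_day)) {
    return(list(confirmed = FALSE, adjudicated_unconfirmed = TRUE,
                failure_day = as.integer(adjudicated_day), pair_days = NULL))
  }
  no
}

#' Per-participant CVF status for a dataset
#'
#' @param ds a [trial_dataset()].
#' @return data frame: `participant_id`, `arm`, `confirmed`,
#'   `adjudicated_unconfirmed`, `failure_day`.
#' @export
cvf_status <- function(ds) {
  p <- ds$participants
  vl_split <- split(ds$viral_loads, ds$viral_loads$participant_id)
  rows <- lapply(seq_len(nrow(p)), function(i) {
    pid <- p$participant_id[[i]]
    st <- detect_cvf(vl_split[[pid]], monitoring_rule(p$arm[[i]]),
                     p$adjudicated_failure_day[[i]])
    data.frame(participant_id = pid, arm = p$arm[[i]],
               confirmed = st$confirmed,
               adjudicated_unconfirmed = st$adjudicated_unconfirmed,
               failure_day = st$failure_day, stringsAsFactors = FALSE)
  })
  if (!length(rows)) {
    return(data.frame(participant_id = character(0), arm = character(0),
                      confirmed = logical(0),
                      adjudicated_unconfirmed = logical(0),
                      failure_day = integer(0), stringsAsFactors = FALSE))
  }
  do.call(rbind, rows)
}

#' Per-arm confirmed-virological-failure counts
#'
#' Counts failures over the ITT-E denominator per arm; adjudicated
#' unconfirmed failures are included when `count_adjudicated = TRUE`.
#'
#' @param ds a [trial_dataset()].
#' @param count_adjudicated include adjudicated unconfirmed failures.
#' @return data frame: `arm`, `failures`, `n`.
#' @export
cvf_table <- function(ds, count_adjudicated = TRUE) {
  st <- cvf_status(ds)
  fail <- st$confirmed | (count_adjudicated & st$adjudicated_unconfirmed)
  out <- lapply(ARM_LEVELS, function(a) {
    data.frame(arm = a, failures = sum(fail[st$arm == a]),
               n = sum(st$arm == a), stringsAsFactors = FALSE)
  })
  do.call(rbind, out)
}
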