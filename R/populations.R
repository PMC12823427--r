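## Analysis-population derivation.
##
## ITT-exposed: received at least one dose of the assigned intervention.
## Per-protocol excludes, in precedence order: withdrawal or death before
## week 96; an injection given more than 14 days after its target date,
## counting only unbridged days; more than 7 missed days of oral treatment
## at one or more visits. Complete-case: ITT-E with a viral load inside the
## snapshot window.

#' Injection delay excluding oral-bridged days
#'
#' Days an injection was given after its target date, minus any days inside
#' an oral-bridging interval that overlap the delay period (bridged days do
#' not count toward the delay). An injection recorded more than the visit
#' window (7 days) before its target raises a warning and counts as delay 0.
#'
#' @param target_day scheduled injection day.
#' @param actual_day day the injection was given.
#' @param bridges optional data frame of bridging intervals with columns
#'   `bridge_start_day`, `bridge_end_day`.
#' @return non-negative integer delay in days.
#' @export
#' @examples
#' injection_delay(392, 412,
#'                 data.frame(bridge_start_day = 392, bridge_end_day = 402))
injection_delay <- function(target_day, actual_day, bridges = NULL) {
  stopifnot(!is.na(target_day), !is.na(actual_day))
  if (actual_day < target_day - 7) {
    warning(sprintf(
      "injection on day %d predates its target day %d by more than the visit window; delay set to 0",
      actual_day, target_day))
    return(0L)
  }
  delay <- actual_day - target_day
  if (delay <= 0) return(0L)
  bridged <- 0
  if (!is.null(bridges) && nrow(bridges)) {
    b <- bridges[!is.na(bridges$bridge_start_day) &
                   !is.na(bridges$bridge_end_day), , drop = FALSE]
    if (nrow(b)) {
      overlap <- pmax(0, pmin(b$bridge_end_day, actual_day) -
                        pmax(b$bridge_start_day, target_day))
      bridged <- sum(overlap)
    }
  }
  max(0L, as.integer(delay - bridged))
}

#' Derive the analysis populations
#'
#' Computes per-participant flags for the intention-to-treat exposed
#' (ITT-E), per-protocol (PP) and complete-case populations, plus a single
#' exclusion reason for each participant outside PP. The fixed precedence
#' (`withdrew_or_died` > `injection_delay_gt14_no_bridge` >
#' `missed_oral_gt7`) gives each excluded participant exactly one reason, so
#' exclusion counts by reason reconstruct the PP size.
#'
#' @param ds a [trial_dataset()].
#' @param config a [snapshot_config()] (defines the complete-case window and
#'   the week-96 day used for the disposition rule).
#' @return data frame: `participant_id`, `arm`, `itt_e`, `per_protocol`,
#'   `complete_case`, `pp_exclusion_reason` (NA when retained).
#' @export
derive_populations <- function(ds, config = snapshot_config()) {
  p <- ds$participants
  d <- ds$doses
  vl <- ds$viral_loads
  week96 <- week_to_day(config$nominal_week)
  w_start <- week_to_day(config$window_start_week)

  dosed <- d[!is.na(d$actual_day), , drop = FALSE]
  itt_e <- p$participant_id %in% dosed$participant_id

  ## disposition rule: withdrew or died strictly before week 96
  term_day <- pmin(ifelse(is.na(p$withdrawal_day), Inf, p$withdrawal_day),
                   ifelse(is.na(p$death_day), Inf, p$death_day))
  withdrew_died <- term_day < week96

  inj <- d[d$kind == "injection" & !is.na(d$actual_day), , drop = FALSE]
  bridges <- d[d$kind == "oral_bridge", , drop = FALSE]
  delay_flag <- logical(nrow(p))
  if (nrow(inj)) {
    inj_split <- split(inj, inj$participant_id)
    br_split <- split(bridges, bridges$participant_id)
    for (pid in names(inj_split)) {
      rows <- inj_split[[pid]]
      br <- br_split[[pid]]
      delays <- vapply(seq_len(nrow(rows)), function(i) {
        injection_delay(rows$target_day[[i]], rows$actual_day[[i]], br)
      }, numeric(1))
      if (any(delays > 14)) {
        delay_flag[match(pid, p$participant_id)] <- TRUE
      }
    }
  }

  oral <- d[d$kind %in% c("oral_dispense", "oral_bridge"), , drop = FALSE]
  missed_ids <- unique(oral$participant_id[!is.na(oral$missed_oral_days) &
                                             oral$missed_oral_days > 7])
  missed_flag <- p$participant_id %in% missed_ids

  reason <- rep(NA_character_, nrow(p))
  reason[missed_flag] <- "missed_oral_gt7"
  reason[delay_flag] <- "injection_delay_gt14_no_bridge"
  reason[withdrew_died] <- "withdrew_or_died"

  per_protocol <- itt_e & is.na(reason)
  reason[!itt_e] <- NA_character_

  ends <- vapply(p$participant_id, window_end_day, numeric(1), config = config)
  vl_end <- ends[match(vl$participant_id, p$participant_id)]
  in_window <- vl$study_day >= w_start & vl$study_day <= vl_end
  has_window_vl <- p$participant_id %in% unique(vl$participant_id[in_window])

  data.frame(
    participant_id = p$participant_id,
    arm = p$arm,
    itt_e = itt_e,
    per_protocol = per_protocol,
    complete_case = itt_e & has_window_vl,
    pp_exclusion_reason = reason,
    stringsAsFactors = FALSE
  )
}

#' Per-arm population summary
#'
#' @param ds a [trial_dataset()].
#' @param config a [snapshot_config()].
#' @return data frame of per-arm population sizes and PP exclusion counts by
#'   reason.
#' @export
population_summary <- function(ds, config = snapshot_config()) {
  flags <- derive_populations(ds, config)
  out <- lapply(ARM_LEVELS, function(a) {
    f <- flags[flags$arm == a, , drop = FALSE]
    data.frame(
      arm = a,
      itt_e = sum(f$itt_e),
      per_protocol = sum(f$per_protocol),
      complete_case = sum(f$complete_case),
      excl_withdrew_or_died = sum(f$pp_exclusion_reason == "withdrew_or_died",
                                  na.rm = TRUE),
      excl_injection_delay = sum(f$pp_exclusion_reason ==
                                   "injection_delay_gt14_no_bridge",
                                 na.rm = TRUE),
      excl_missed_oral = sum(f$pp_exclusion_reason == "missed_oral_gt7",
                             na.rm = TRUE),
      stringsAsFactors = FALSE
    )
  })
  do.call(rbind, out)
}
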