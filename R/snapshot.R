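## Modified FDA snapshot classification of the week-96 virologic outcome.
##
## Each participant is classified as suppressed, nonsuppressed or no_data
## from the viral load measured inside a prespecified window (weeks 84-102,
## days 588-714 inclusive), with three modifications to what counts as a
## treatment switch: temporary regimen changes of at most 31 days, oral
## bridging of the long-acting drugs with a return to injections, and
## within-class drug changes in the oral arm are not switches. A switch made
## for virological failure before the end of the window assigns the
## participant to nonsuppressed regardless of any in-window measurement.

#' Snapshot classification settings
#'
#' @param threshold suppression threshold in copies/ml (50 for the primary
#'   outcome; 200 for the secondary suppression outcome).
#' @param window_start_week,window_end_week measurement window, inclusive
#'   nominal weeks (days `7*start` to `7*end`).
#' @param nominal_week the target visit week; when several measurements fall
#'   in the window the one closest in study days to `7*nominal_week` is
#'   used, ties resolved toward the later measurement.
#' @param temporary_change_max_days longest regimen change still counted as
#'   temporary (not a switch).
#' @param window_extensions optional data frame (`participant_id`,
#'   `extended_end_week`) extending the window end for named participants
#'   (e.g. a deliberately delayed test kept in the analysis to avoid
#'   selective exclusion in one arm).
#' @return a `snapshot_config` list.
#' @export
snapshot_config <- function(threshold = 50,
                            window_start_week = 84,
                            window_end_week = 102,
                            nominal_week = 96,
                            temporary_change_max_days = 31,
                            window_extensions = NULL) {
  stopifnot(threshold > 0,
            window_start_week < nominal_week,
            nominal_week < window_end_week)
  if (!is.null(window_extensions)) {
    stopifnot(is.data.frame(window_extensions),
              all(c("participant_id", "extended_end_week") %in%
                    names(window_extensions)))
  }
  structure(
    list(threshold = threshold,
         window_start_week = window_start_week,
         window_end_week = window_end_week,
         nominal_week = nominal_week,
         temporary_change_max_days = temporary_change_max_days,
         window_extensions = window_extensions),
    class = "snapshot_config"
  )
}

#' Identify a disqualifying treatment switch
#'
#' Scans a participant's regimen changes (sorted by `start_day`) and returns
#' whether any constitutes a treatment switch under the modified snapshot
#' rules. A change is *not* a switch when it is (a) temporary, i.e. closed
#' within `temporary_change_max_days`; (b) a move to the oral forms of the
#' long-acting drugs (bridging) that ends, i.e. injections resume; or (c) a
#' within-class change in the oral arm.
#'
#' @param changes data frame of the participant's regimen-change rows.
#' @param arm the participant's arm (`"long_acting"` or `"oral"`).
#' @param config a [snapshot_config()].
#' @return list with `disqualifying` (logical) and `change` (the first
#'   qualifying row, or `NULL`).
#' @export
is_disqualifying_switch <- function(changes, arm, config = snapshot_config()) {
  if (is.null(changes) || !nrow(changes)) {
    return(list(disqualifying = FALSE, change = NULL))
  }
  changes <- changes[order(changes$start_day), , drop = FALSE]
  open <- is.na(changes$end_day)
  if (sum(open) > 1L) {
    vs_stop("virosnap_integrity_error",
            "participant '%s' has overlapping open-ended regimen changes",
            changes$participant_id[[1L]])
  }
  for (i in seq_len(nrow(changes))) {
    ch <- changes[i, , drop = FALSE]
    temporary <- !is.na(ch$end_day) &&
      (ch$end_day - ch$start_day) <= config$temporary_change_max_days
    if (temporary) next
    bridging <- isTRUE(ch$to_long_acting_oral_forms) && !is.na(ch$end_day)
    if (bridging) next
    if (arm == "oral" && isTRUE(ch$within_class)) next
    return(list(disqualifying = TRUE, change = ch))
  }
  list(disqualifying = FALSE, change = NULL)
}

## window end for one participant, honouring extensions
window_end_day <- function(participant_id, config) {
  ext <- config$window_extensions
  if (!is.null(ext)) {
    hit <- match(participant_id, ext$participant_id)
    if (!is.na(hit)) return(week_to_day(ext$extended_end_week[[hit]]))
  }
  week_to_day(config$window_end_week)
}

vl_below <- function(vl_row, threshold) {
  if (isTRUE(vl_row$below_lloq)) return(TRUE)
  if (is.na(vl_row$copies_per_ml)) {
    vs_stop("virosnap_schema_error",
            "quantified viral load missing for participant '%s'",
            vl_row$participant_id)
  }
  vl_row$copies_per_ml < threshold
}

#' Classify one participant's snapshot outcome
#'
#' Applies the modified snapshot algorithm to one participant bundle. The
#' order of precedence is: (1) a disqualifying switch made for virological
#' failure before the end of the window assigns `nonsuppressed`
#' (`assigned_failure_switch`) regardless of any in-window measurement;
#' (2) a disqualifying switch for any other reason yields `no_data` with the
#' disposition-derived reason; (3) otherwise the selected in-window
#' measurement decides suppressed/nonsuppressed against the threshold;
#' (4) with no in-window measurement the participant is `no_data` with
#' reason `death` > `withdrawal` > `missing_in_window`.
#'
#' @param participant one-row data frame from the participants table.
#' @param viral_loads the participant's viral-load rows.
#' @param changes the participant's regimen-change rows.
#' @param config a [snapshot_config()].
#' @return one-row data frame: `participant_id`, `category`, `reason`,
#'   `vl_day`, `vl_copies`, `vl_below_lloq`.
#' @export
classify_snapshot <- function(participant, viral_loads, changes,
                              config = snapshot_config()) {
  pid <- participant$participant_id
  w_start <- week_to_day(config$window_start_week)
  w_end <- window_end_day(pid, config)
  nominal_day <- week_to_day(config$nominal_week)

  result <- function(category, reason, vl = NULL) {
    data.frame(
      participant_id = pid, category = category, reason = reason,
      vl_day = if (is.null(vl)) NA_integer_ else vl$study_day,
      vl_copies = if (is.null(vl)) NA_integer_ else vl$copies_per_ml,
      vl_below_lloq = if (is.null(vl)) NA else vl$below_lloq,
      stringsAsFactors = FALSE
    )
  }
  disposition_reason <- function() {
    if (!is.na(participant$death_day) && participant$death_day <= w_end) {
      "death"
    } else if (!is.na(participant$withdrawal_day) &&
               participant$withdrawal_day <= w_end) {
      "withdrawal"
    } else {
      "missing_in_window"
    }
  }

  sw <- is_disqualifying_switch(changes, participant$arm, config)
  if (sw$disqualifying && sw$change$start_day <= w_end) {
    if (sw$change$reason == "virological_failure") {
      return(result("nonsuppressed", "assigned_failure_switch"))
    }
    return(result("no_data", disposition_reason()))
  }

  vl <- viral_loads[viral_loads$study_day >= w_start &
                      viral_loads$study_day <= w_end, , drop = FALSE]
  if (nrow(vl)) {
    dist <- abs(vl$study_day - nominal_day)
    ## ties toward the later measurement
    pick <- order(dist, -vl$study_day)[[1L]]
    sel <- vl[pick, , drop = FALSE]
    category <- if (vl_below(sel, config$threshold)) "suppressed" else "nonsuppressed"
    return(result(category, "observed_vl", sel))
  }
  result("no_data", disposition_reason())
}

#' Classify every participant in a dataset
#'
#' @param ds a [trial_dataset()].
#' @param config a [snapshot_config()].
#' @return data frame with one classification row per participant, plus the
#'   participant's `arm`.
#' @export
snapshot_classify <- function(ds, config = snapshot_config()) {
  p <- ds$participants
  if (!nrow(p)) {
    return(data.frame(participant_id = character(0), category = character(0),
                      reason = character(0), vl_day = integer(0),
                      vl_copies = integer(0), vl_below_lloq = logical(0),
                      arm = character(0), stringsAsFactors = FALSE))
  }
  vl_split <- split(ds$viral_loads, ds$viral_loads$participant_id)
  rc_split <- split(ds$regimen_changes, ds$regimen_changes$participant_id)
  rows <- vector("list", nrow(p))
  for (i in seq_len(nrow(p))) {
    pid <- p$participant_id[[i]]
    rows[[i]] <- classify_snapshot(
      p[i, , drop = FALSE],
      vl_split[[pid]] %||% empty_table("viral_loads"),
      rc_split[[pid]] %||% empty_table("regimen_changes"),
      config
    )
  }
  out <- do.call(rbind, rows)
  out$arm <- p$arm[match(out$participant_id, p$participant_id)]
  out
}

#' Per-arm snapshot outcome table
#'
#' Counts suppressed / nonsuppressed / no-virologic-data participants per
#' arm. The three counts always partition the arm.
#'
#' @param ds a [trial_dataset()].
#' @param config a [snapshot_config()].
#' @return data frame with columns `arm`, `suppressed`, `nonsuppressed`,
#'   `no_data`, `n`.
#' @export
snapshot_table <- function(ds, config = snapshot_config()) {
  cls <- snapshot_classify(ds, config)
  out <- lapply(ARM_LEVELS, function(a) {
    sub <- cls[cls$arm == a, , drop = FALSE]
    data.frame(
      arm = a,
      suppressed = sum(sub$category == "suppressed"),
      nonsuppressed = sum(sub$category == "nonsuppressed"),
      no_data = sum(sub$category == "no_data"),
      n = nrow(sub),
      stringsAsFactors = FALSE
    )
  })
  do.call(rbind, out)
}
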