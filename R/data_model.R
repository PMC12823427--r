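## Participant-level data model shared by all analysis stages.
##
## All tables are keyed by participant_id and use an integer study-day axis:
## randomization is day 0 and nominal week w is day 7*w. Censored viral loads
## (reported as "<50") are stored with below_lloq = TRUE and copies_per_ml = 0
## so that threshold comparisons consult the censoring flag first and never a
## sentinel value.

ARM_LEVELS <- c("long_acting", "oral")
STRATUM_LEVELS <- c("INSTI", "NNRTI")
DOSE_KINDS <- c("injection", "oral_dispense", "oral_bridge")
CHANGE_REASONS <- c("virological_failure", "adverse_event", "other")
SEQ_TIMEPOINTS <- c("baseline", "failure")
GENE_LEVELS <- c("RT", "IN")

## column name -> storage mode, per table; the single source of truth for
## readers, writers and validation
vs_schema <- function() {
  list(
    participants = c(
      participant_id = "character", arm = "character", stratum = "character",
      randomization_day = "integer", withdrawal_day = "integer",
      death_day = "integer", oral_lead_in = "logical", sex = "character",
      baseline_bmi = "numeric", adjudicated_failure_day = "integer",
      adjudication_note = "character"
    ),
    viral_loads = c(
      participant_id = "character", study_day = "integer",
      nominal_week = "integer", copies_per_ml = "integer",
      below_lloq = "logical"
    ),
    doses = c(
      participant_id = "character", kind = "character",
      target_day = "integer", actual_day = "integer",
      missed_oral_days = "integer", bridge_start_day = "integer",
      bridge_end_day = "integer"
    ),
    regimen_changes = c(
      participant_id = "character", start_day = "integer",
      end_day = "integer", within_class = "logical", reason = "character",
      to_long_acting_oral_forms = "logical"
    ),
    adverse_events = c(
      participant_id = "character", onset_day = "integer", grade = "integer",
      serious = "logical", related = "logical", injection_site = "logical",
      led_to_discontinuation = "logical"
    ),
    sequences = c(
      participant_id = "character", timepoint = "character",
      gene = "character", residues = "character"
    ),
    mutation_calls = c(
      participant_id = "character", timepoint = "character",
      gene = "character", mutation = "character"
    )
  )
}

empty_table <- function(name) {
  spec <- vs_schema()[[name]]
  out <- lapply(spec, function(mode) vector(mode, 0L))
  as.data.frame(out, stringsAsFactors = FALSE)
}

coerce_table <- function(df, name) {
  spec <- vs_schema()[[name]]
  missing <- setdiff(names(spec), names(df))
  if (length(missing)) {
    vs_stop("virosnap_schema_error",
            "table '%s' is missing column '%s'", name, missing[[1L]])
  }
  df <- df[names(spec)]
  for (col in names(spec)) {
    mode <- spec[[col]]
    df[[col]] <- switch(mode,
      integer = as.integer(df[[col]]),
      numeric = as.numeric(df[[col]]),
      logical = as.logical(df[[col]]),
      character = as.character(df[[col]])
    )
  }
  rownames(df) <- NULL
  df
}

check_enum <- function(values, levels, table, column) {
  bad <- setdiff(unique(values[!is.na(values)]), levels)
  if (length(bad)) {
    vs_stop("virosnap_schema_error",
            "table '%s' column '%s' has invalid value '%s' (allowed: %s)",
            table, column, bad[[1L]], paste(levels, collapse = ", "))
  }
  invisible(TRUE)
}

#' Assemble and validate a trial dataset
#'
#' Bundles the participant-level tables into a single validated object of
#' class `trial_dataset`. Missing optional tables default to empty. The
#' constructor enforces the schema (column names and storage modes),
#' categorical levels, per-table invariants (censored viral loads below the
#' assay limit, well-ordered bridging intervals, adverse-event grades 1-4,
#' zero missed oral days on injections), key uniqueness, and referential
#' integrity of `participant_id` across tables.
#'
#' @param participants data frame of participant records (one row each):
#'   `participant_id`, `arm` (`long_acting`/`oral`), `stratum`
#'   (`INSTI`/`NNRTI`, third-drug class at screening), `randomization_day`,
#'   optional `withdrawal_day`/`death_day`, `oral_lead_in`, `sex`,
#'   `baseline_bmi`, and optional adjudication fields
#'   (`adjudicated_failure_day`, `adjudication_note`) recording a clinical
#'   adjudication of an unconfirmed failure.
#' @param viral_loads viral-load measurements: `study_day`, `nominal_week`,
#'   `copies_per_ml`, `below_lloq` (TRUE for values reported as "<50").
#' @param doses injection/dispensing events: `kind`, `target_day`,
#'   `actual_day` (NA = missed), `missed_oral_days`, and bridging interval
#'   `bridge_start_day`/`bridge_end_day` for `oral_bridge` rows.
#' @param regimen_changes regimen-change episodes: `start_day`, `end_day`
#'   (NA = open-ended), `within_class`, `reason`,
#'   `to_long_acting_oral_forms`.
#' @param adverse_events graded adverse events.
#' @param sequences amino-acid sequence records (`timepoint`, `gene`,
#'   `residues`; mixtures written as bracket groups, e.g. `"A[NS]C"`).
#' @param mutation_calls mutation-call table in standard notation
#'   (e.g. `"K103N/S"`).
#' @return a `trial_dataset`: a named list of the seven validated tables.
#' @export
trial_dataset <- function(participants,
                          viral_loads = empty_table("viral_loads"),
                          doses = empty_table("doses"),
                          regimen_changes = empty_table("regimen_changes"),
                          adverse_events = empty_table("adverse_events"),
                          sequences = empty_table("sequences"),
                          mutation_calls = empty_table("mutation_calls")) {
  ds <- list(
    participants = coerce_table(participants, "participants"),
    viral_loads = coerce_table(viral_loads, "viral_loads"),
    doses = coerce_table(doses, "doses"),
    regimen_changes = coerce_table(regimen_changes, "regimen_changes"),
    adverse_events = coerce_table(adverse_events, "adverse_events"),
    sequences = coerce_table(sequences, "sequences"),
    mutation_calls = coerce_table(mutation_calls, "mutation_calls")
  )
  validate_trial_dataset(ds)
  structure(ds, class = "trial_dataset")
}

#' Validate a trial dataset
#'
#' Checks the invariants documented in [trial_dataset()]. Called by the
#' constructor; exported so that datasets modified in place can be
#' re-checked.
#'
#' @param ds a `trial_dataset` or compatible named list of tables.
#' @return the dataset, invisibly; errors of class `virosnap_schema_error` or
#'   `virosnap_integrity_error` otherwise.
#' @export
validate_trial_dataset <- function(ds) {
  p <- ds$participants
  if (anyDuplicated(p$participant_id)) {
    vs_stop("virosnap_integrity_error", "duplicate participant_id '%s'",
            p$participant_id[duplicated(p$participant_id)][[1L]])
  }
  check_enum(p$arm, ARM_LEVELS, "participants", "arm")
  check_enum(p$stratum, STRATUM_LEVELS, "participants", "stratum")
  check_enum(p$sex, c("female", "male"), "participants", "sex")
  for (col in c("withdrawal_day", "death_day")) {
    bad <- which(!is.na(p[[col]]) & p[[col]] < 0)
    if (length(bad)) {
      vs_stop("virosnap_schema_error",
              "participants: %s must be >= 0 (participant '%s')",
              col, p$participant_id[bad[[1L]]])
    }
  }

  vl <- ds$viral_loads
  if (nrow(vl)) {
    if (any(is.na(vl$below_lloq))) {
      vs_stop("virosnap_schema_error", "viral_loads: below_lloq must not be NA")
    }
    bad <- which(!vl$below_lloq & is.na(vl$copies_per_ml))
    if (length(bad)) {
      vs_stop("virosnap_schema_error",
              "viral_loads: quantified value missing for participant '%s'",
              vl$participant_id[bad[[1L]]])
    }
    bad <- which(vl$below_lloq & !is.na(vl$copies_per_ml) & vl$copies_per_ml >= 50)
    if (length(bad)) {
      vs_stop("virosnap_schema_error",
              "viral_loads: below_lloq row with copies_per_ml >= 50 (participant '%s')",
              vl$participant_id[bad[[1L]]])
    }
    if (any(vl$study_day < 0, na.rm = TRUE)) {
      vs_stop("virosnap_schema_error", "viral_loads: study_day must be >= 0")
    }
    key <- paste(vl$participant_id, vl$study_day, sep = "\r")
    if (anyDuplicated(key)) {
      dup <- vl[duplicated(key), , drop = FALSE]
      vs_stop("virosnap_integrity_error",
              "viral_loads: duplicate measurement for participant '%s' on day %d",
              dup$participant_id[[1L]], dup$study_day[[1L]])
    }
  }

  d <- ds$doses
  if (nrow(d)) {
    check_enum(d$kind, DOSE_KINDS, "doses", "kind")
    bad <- which(d$kind == "injection" & d$missed_oral_days != 0)
    if (length(bad)) {
      vs_stop("virosnap_schema_error",
              "doses: missed_oral_days must be 0 on injections (participant '%s')",
              d$participant_id[bad[[1L]]])
    }
    bad <- which(!is.na(d$bridge_start_day) & !is.na(d$bridge_end_day) &
                   d$bridge_end_day < d$bridge_start_day)
    if (length(bad)) {
      vs_stop("virosnap_schema_error",
              "doses: bridge interval not well-ordered (participant '%s')",
              d$participant_id[bad[[1L]]])
    }
    key <- paste(d$participant_id, d$target_day, d$kind, sep = "\r")
    if (anyDuplicated(key)) {
      dup <- d[duplicated(key), , drop = FALSE]
      vs_stop("virosnap_integrity_error",
              "doses: duplicate (participant, target_day, kind) row for '%s' day %d",
              dup$participant_id[[1L]], dup$target_day[[1L]])
    }
  }

  rc <- ds$regimen_changes
  if (nrow(rc)) {
    check_enum(rc$reason, CHANGE_REASONS, "regimen_changes", "reason")
    bad <- which(!is.na(rc$end_day) & rc$end_day < rc$start_day)
    if (length(bad)) {
      vs_stop("virosnap_schema_error",
              "regimen_changes: end_day before start_day (participant '%s')",
              rc$participant_id[bad[[1L]]])
    }
  }

  ae <- ds$adverse_events
  if (nrow(ae) && any(!ae$grade %in% 1:4)) {
    vs_stop("virosnap_schema_error", "adverse_events: grade must be 1, 2, 3 or 4")
  }

  sq <- ds$sequences
  if (nrow(sq)) {
    check_enum(sq$timepoint, SEQ_TIMEPOINTS, "sequences", "timepoint")
    check_enum(sq$gene, GENE_LEVELS, "sequences", "gene")
    key <- paste(sq$participant_id, sq$timepoint, sq$gene, sep = "\r")
    if (anyDuplicated(key)) {
      vs_stop("virosnap_integrity_error",
              "sequences: duplicate (participant, timepoint, gene) record")
    }
  }
  mc <- ds$mutation_calls
  if (nrow(mc)) {
    check_enum(mc$timepoint, SEQ_TIMEPOINTS, "mutation_calls", "timepoint")
    check_enum(mc$gene, GENE_LEVELS, "mutation_calls", "gene")
  }

  ids <- p$participant_id
  for (name in c("viral_loads", "doses", "regimen_changes", "adverse_events",
                 "sequences", "mutation_calls")) {
    orphan <- setdiff(unique(ds[[name]]$participant_id), ids)
    if (length(orphan)) {
      vs_stop("virosnap_integrity_error",
              "table '%s' references unknown participant_id '%s'",
              name, orphan[[1L]])
    }
  }
  invisible(ds)
}

#' @export
print.trial_dataset <- function(x, ...) {
  p <- x$participants
  cat(sprintf("<trial_dataset> %d participants (%d long-acting, %d oral)\n",
              nrow(p), sum(p$arm == "long_acting"), sum(p$arm == "oral")))
  cat(sprintf("  viral loads: %d | doses: %d | regimen changes: %d | AEs: %d\n",
              nrow(x$viral_loads), nrow(x$doses), nrow(x$regimen_changes),
              nrow(x$adverse_events)))
  if (nrow(x$sequences)) {
    cat(sprintf("  sequences: %d | mutation calls: %d\n",
                nrow(x$sequences), nrow(x$mutation_calls)))
  }
  invisible(x)
}
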