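## Plain-text persistence: one CSV per table, plus a FASTA file for residues.
## CSV dialect is fixed (comma separator, UTF-8, header row, blank = NA) so
## round trips are locale independent.

table_files <- c(
  participants = "participants.csv",
  viral_loads = "viral_loads.csv",
  doses = "doses.csv",
  regimen_changes = "regimen_changes.csv",
  adverse_events = "adverse_events.csv",
  sequences = "sequences.csv"
)
FASTA_FILE <- "sequences.fasta"
CALLS_FILE <- "mutation_calls.csv"

#' Write a trial dataset to a directory
#'
#' Persists every table as a CSV file (`participants.csv`,
#' `viral_loads.csv`, `doses.csv`, `regimen_changes.csv`,
#' `adverse_events.csv`, `sequences.csv`). Amino-acid residues are written to
#' `sequences.fasta` with record ids `participant_id|timepoint|gene`;
#' `mutation_calls.csv` is written only when calls are present. The output is
#' re-readable by [read_trial_dataset()] with field-level equality.
#'
#' @param ds a [trial_dataset()].
#' @param dir output directory, created if needed.
#' @return the vector of files written, invisibly.
#' @export
write_trial_dataset <- function(ds, dir) {
  stopifnot(inherits(ds, "trial_dataset"))
  if (!dir.exists(dir)) {
    ok <- dir.create(dir, recursive = TRUE, showWarnings = FALSE)
    if (!ok) vs_stop("virosnap_io_error", "cannot create directory '%s'", dir)
  }
  written <- character(0)
  for (name in names(table_files)) {
    tab <- ds[[name]]
    if (name == "sequences") tab <- tab[setdiff(names(tab), "residues")]
    path <- file.path(dir, table_files[[name]])
    utils::write.csv(tab, path, row.names = FALSE, na = "", quote = TRUE,
                     fileEncoding = "UTF-8")
    written <- c(written, path)
  }
  if (nrow(ds$sequences)) {
    sq <- ds$sequences
    ids <- paste(sq$participant_id, sq$timepoint, sq$gene, sep = "|")
    path <- file.path(dir, FASTA_FILE)
    seqinr::write.fasta(as.list(sq$residues), names = ids, file.out = path,
                        as.string = TRUE, nbchar = 60)
    written <- c(written, path)
  }
  if (nrow(ds$mutation_calls)) {
    path <- file.path(dir, CALLS_FILE)
    utils::write.csv(ds$mutation_calls, path, row.names = FALSE, na = "",
                     quote = TRUE, fileEncoding = "UTF-8")
    written <- c(written, path)
  }
  invisible(written)
}

read_one_csv <- function(dir, file, name) {
  path <- file.path(dir, file)
  if (!file.exists(path)) {
    vs_stop("virosnap_io_error", "missing input file '%s'", path)
  }
  spec <- vs_schema()[[name]]
  if (name == "sequences") spec <- spec[setdiff(names(spec), "residues")]
  header <- names(utils::read.csv(path, nrows = 1, check.names = FALSE))
  if (nrow_csv_empty(path)) {
    ## header-only file: build typed empty table
    df <- empty_table(name)
    missing <- setdiff(names(spec), header)
    if (length(missing)) {
      vs_stop("virosnap_schema_error", "table '%s' is missing column '%s'",
              name, missing[[1L]])
    }
    return(df[names(df) %in% c(names(spec), "residues")])
  }
  classes <- unname(vapply(spec, function(m) m, character(1)))
  missing <- setdiff(names(spec), header)
  if (length(missing)) {
    vs_stop("virosnap_schema_error", "table '%s' is missing column '%s'",
            name, missing[[1L]])
  }
  df <- utils::read.csv(path, colClasses = setNames(classes, names(spec)),
                        na.strings = "", fileEncoding = "UTF-8",
                        check.names = FALSE)
  df[names(spec)]
}

nrow_csv_empty <- function(path) {
  length(readLines(path, n = 2L, warn = FALSE)) < 2L
}

#' Read a trial dataset from a directory
#'
#' Reads the file set written by [write_trial_dataset()] and returns a
#' validated [trial_dataset()]. Column sets are checked against the schema
#' (a missing column raises a schema error naming it) and cross-table
#' referential integrity is enforced (an orphan `participant_id` raises an
#' integrity error).
#'
#' @param dir directory containing the CSV files (and optional FASTA).
#' @return a `trial_dataset`.
#' @export
read_trial_dataset <- function(dir) {
  tabs <- lapply(names(table_files), function(name) {
    read_one_csv(dir, table_files[[name]], name)
  })
  names(tabs) <- names(table_files)

  sq <- tabs$sequences
  fasta_path <- file.path(dir, FASTA_FILE)
  if (nrow(sq)) {
    if (!file.exists(fasta_path)) {
      vs_stop("virosnap_io_error",
              "sequences.csv has records but '%s' is missing", fasta_path)
    }
    recs <- seqinr::read.fasta(fasta_path, seqtype = "AA", as.string = TRUE,
                               forceDNAtolower = FALSE)
    rec_ids <- names(recs)
    want <- paste(sq$participant_id, sq$timepoint, sq$gene, sep = "|")
    miss <- setdiff(want, rec_ids)
    if (length(miss)) {
      vs_stop("virosnap_integrity_error",
              "FASTA record '%s' missing for sequence metadata row", miss[[1L]])
    }
    sq$residues <- vapply(want, function(id) as.character(recs[[id]][[1L]]),
                          character(1), USE.NAMES = FALSE)
  } else {
    sq$residues <- character(0)
  }
  tabs$sequences <- sq

  calls_path <- file.path(dir, CALLS_FILE)
  calls <- if (file.exists(calls_path)) {
    read_one_csv(dir, CALLS_FILE, "mutation_calls")
  } else {
    empty_table("mutation_calls")
  }

  trial_dataset(
    participants = tabs$participants,
    viral_loads = tabs$viral_loads,
    doses = tabs$doses,
    regimen_changes = tabs$regimen_changes,
    adverse_events = tabs$adverse_events,
    sequences = tabs$sequences,
    mutation_calls = calls
  )
}
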