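## Drug-resistance mutation calls and APOBEC-context filtering.
##
## Host APOBEC enzymes hypermutate archived proviral DNA (G-to-A), which can
## create apparent drug-resistance mutations on virus that is in fact
## defective. A curated set of 14 "APOBEC-context" resistance mutations in
## reverse transcriptase (RT) and integrase (IN) is therefore disregarded
## whenever the carrying sequence shows independent evidence of APOBEC
## activity: at least one signature hypermutation or at least one stop
## codon. All other listed mutations are retained regardless of evidence.
##
## Residue strings use one character per reference position; an ambiguous
## position (amino-acid mixture) is written as a bracket group, e.g.
## "PIS[NS]ETP" has an N/S mixture at position 4. '*' denotes a stop codon.

#' Load mutation reference lists
#'
#' Reads the reference lists the filter consults: the drug-resistance
#' mutation (DRM) list (gene, position, mutant amino acid, drug), the
#' APOBEC-context DRM set, and the per-gene APOBEC signature-mutation lists.
#' The shipped context set is the standard 14-item set (RT 67N, 138K, 184I,
#' 190E, 190S, 230I; IN 118R, 138K, 140R, 140S, 163K, 163R, 232N, 263K).
#' The shipped DRM and signature files are small synthetic defaults
#' sufficient for simulation and testing; analyses of real sequences should
#' supply files transcribed from the curated public databases.
#'
#' @param drm_file CSV with columns `gene`, `position`, `aa`, `drug`.
#' @param context_file CSV with columns `gene`, `position`, `aa`.
#' @param signature_file CSV with columns `gene`, `position`, `aa`.
#' @return a `mutation_lists` list with elements `drm`, `context`,
#'   `signatures`, `stop_codon_symbol`.
#' @export
mutation_lists <- function(
    drm_file = system.file("extdata", "drm_list_synthetic.csv",
                           package = "virosnap"),
    context_file = system.file("extdata", "apobec_context_drms.csv",
                               package = "virosnap"),
    signature_file = system.file("extdata", "apobec_signatures_synthetic.csv",
                                 package = "virosnap")) {
  read_list <- function(path, cols) {
    df <- utils::read.csv(path, stringsAsFactors = FALSE)
    missing <- setdiff(cols, names(df))
    if (length(missing)) {
      vs_stop("virosnap_schema_error", "mutation list '%s' missing column '%s'",
              path, missing[[1L]])
    }
    df$position <- as.integer(df$position)
    df
  }
  structure(
    list(
      drm = read_list(drm_file, c("gene", "position", "aa", "drug")),
      context = read_list(context_file, c("gene", "position", "aa")),
      signatures = read_list(signature_file, c("gene", "position", "aa")),
      stop_codon_symbol = "*"
    ),
    class = "mutation_lists"
  )
}

#' Parse a mutation call in standard notation
#'
#' Accepts `RefAA? Position ObservedAA(/ObservedAA)*`, e.g. `"K103N"`,
#' `"K103N/S"`, `"103N"`. In a mixture the reference letter is dropped from
#' mutant matching, so `"M230M/L"` yields observed set `{L}`.
#'
#' @param text the mutation string.
#' @param gene `"RT"` or `"IN"`.
#' @return list: `gene`, `position`, `reference_aa` (`NA` if absent),
#'   `observed_aas` (character vector).
#' @export
#' @examples
#' parse_mutation("K103N/S", "RT")
parse_mutation <- function(text, gene) {
  stopifnot(gene %in% GENE_LEVELS)
  m <- regexec("^([A-Z]?)([0-9]+)([A-Z*](?:/[A-Z*])*)$", text)[[1L]]
  if (m[[1L]] == -1L) {
    ## locate the first offending character for the error message
    ok <- regexpr("^[A-Z]?[0-9]+[A-Z*](/[A-Z*])*", text)
    offset <- if (ok == -1L) 1L else attr(ok, "match.length") + 1L
    vs_stop("virosnap_parse_error",
            "malformed mutation call '%s' (offset %d)", text, offset)
  }
  parts <- regmatches(text, list(m))[[1L]]
  ref <- if (nzchar(parts[[2L]])) parts[[2L]] else NA_character_
  observed <- unique(strsplit(parts[[4L]], "/", fixed = TRUE)[[1L]])
  mutants <- setdiff(observed, ref)
  if (!length(mutants)) mutants <- observed  # pure-reference call
  list(gene = gene, position = as.integer(parts[[3L]]),
       reference_aa = ref, observed_aas = mutants)
}

## residue string -> list of per-position character sets; bracket groups are
## mixtures
parse_residues <- function(residues) {
  chars <- strsplit(residues, "", fixed = TRUE)[[1L]]
  out <- list()
  i <- 1L
  while (i <= length(chars)) {
    if (chars[[i]] == "[") {
      close <- i + 1L
      while (close <= length(chars) && chars[[close]] != "]") close <- close + 1L
      if (close > length(chars)) {
        vs_stop("virosnap_parse_error",
                "unterminated mixture bracket in residue string (offset %d)", i)
      }
      out[[length(out) + 1L]] <- chars[(i + 1L):(close - 1L)]
      i <- close + 1L
    } else {
      out[[length(out) + 1L]] <- chars[[i]]
      i <- i + 1L
    }
  }
  out
}

#' Test a sequence for evidence of APOBEC activity
#'
#' A sequence shows APOBEC evidence when it carries at least one signature
#' hypermutation from the per-gene signature list, or at least one stop
#' codon (`*`).
#'
#' @param residues residue string (see package notes on mixture notation).
#' @param gene `"RT"` or `"IN"`.
#' @param lists a [mutation_lists()].
#' @return list: `evidence` (logical), `kind` (`"signature_mutation"`,
#'   `"stop_codon"` or `"none"`).
#' @export
has_apobec_evidence <- function(residues, gene, lists) {
  pos_sets <- parse_residues(residues)
  sig <- lists$signatures[lists$signatures$gene == gene, , drop = FALSE]
  if (nrow(sig)) {
    for (i in seq_len(nrow(sig))) {
      p <- sig$position[[i]]
      if (p <= length(pos_sets) && sig$aa[[i]] %in% pos_sets[[p]]) {
        return(list(evidence = TRUE, kind = "signature_mutation"))
      }
    }
  }
  if (any(vapply(pos_sets, function(s) lists$stop_codon_symbol %in% s,
                 logical(1)))) {
    return(list(evidence = TRUE, kind = "stop_codon"))
  }
  list(evidence = FALSE, kind = "none")
}

#' Apply the APOBEC-context filter to a sequence's mutation calls
#'
#' A call is disregarded if and only if one of its observed mutants matches
#' the APOBEC-context DRM set at that gene and position *and* the carrying
#' sequence shows APOBEC evidence. All other calls are retained. The filter
#' is idempotent and never increases the retained set.
#'
#' @param calls list of parsed calls ([parse_mutation()]) for one sequence.
#' @param residues the sequence's residue string.
#' @param gene `"RT"` or `"IN"`.
#' @param lists a [mutation_lists()].
#' @return list: `retained`, `disregarded` (lists of calls),
#'   `apobec_evidence` (logical), `evidence_kind`.
#' @export
filter_drms <- function(calls, residues, gene, lists) {
  ev <- has_apobec_evidence(residues, gene, lists)
  ctx <- lists$context[lists$context$gene == gene, , drop = FALSE]
  in_context <- vapply(calls, function(call) {
    any(ctx$position == call$position & ctx$aa %in% call$observed_aas)
  }, logical(1))
  drop <- ev$evidence & in_context
  if (!length(calls)) drop <- logical(0)
  list(
    retained = calls[!drop],
    disregarded = calls[drop],
    apobec_evidence = ev$evidence,
    evidence_kind = ev$kind
  )
}

## drug -> gene it acts on, derived from the DRM list
drug_gene <- function(lists, drug) {
  genes <- unique(lists$drm$gene[lists$drm$drug == drug])
  if (length(genes) != 1L) {
    vs_stop("virosnap_domain_error",
            "drug '%s' must map to exactly one gene in the DRM list", drug)
  }
  genes
}

#' Baseline resistance prevalence with or without the APOBEC filter
#'
#' Fraction of participants carrying at least one retained drug-resistance
#' mutation for `drug`, among participants with a sequence for the relevant
#' gene at the given timepoint. With `apply_filter = FALSE` the
#' APOBEC-context filter is skipped (all listed calls count), which can only
#' increase the prevalence.
#'
#' @param ds a [trial_dataset()] with sequences and mutation calls.
#' @param lists a [mutation_lists()].
#' @param drug drug name as used in the DRM list (e.g. `"rilpivirine"`).
#' @param arm optional arm restriction (`"long_acting"`, `"oral"` or `NULL`
#'   for all).
#' @param timepoint `"baseline"` or `"failure"`.
#' @param apply_filter apply the APOBEC-context filter.
#' @return list: `numerator`, `denominator`, `prevalence`.
#' @export
resistance_prevalence <- function(ds, lists, drug, arm = NULL,
                                  timepoint = "baseline",
                                  apply_filter = TRUE) {
  gene <- drug_gene(lists, drug)
  sq <- ds$sequences
  sq <- sq[sq$gene == gene & sq$timepoint == timepoint, , drop = FALSE]
  if (!is.null(arm)) {
    p <- ds$participants
    keep <- p$participant_id[p$arm == arm]
    sq <- sq[sq$participant_id %in% keep, , drop = FALSE]
  }
  denominator <- nrow(sq)
  if (!denominator) {
    return(list(numerator = 0L, denominator = 0L, prevalence = NA_real_))
  }
  drm <- lists$drm[lists$drm$drug == drug & lists$drm$gene == gene, ,
                   drop = FALSE]
  mc <- ds$mutation_calls
  mc <- mc[mc$gene == gene & mc$timepoint == timepoint, , drop = FALSE]
  numerator <- 0L
  for (i in seq_len(nrow(sq))) {
    pid <- sq$participant_id[[i]]
    texts <- mc$mutation[mc$participant_id == pid]
    if (!length(texts)) next
    calls <- lapply(texts, parse_mutation, gene = gene)
    kept <- if (apply_filter) {
      filter_drms(calls, sq$residues[[i]], gene, lists)$retained
    } else {
      calls
    }
    hit <- any(vapply(kept, function(call) {
      any(drm$position == call$position & drm$aa %in% call$observed_aas)
    }, logical(1)))
    if (hit) numerator <- numerator + 1L
  }
  list(numerator = numerator, denominator = denominator,
       prevalence = numerator / denominator)
}
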