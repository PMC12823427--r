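## End-to-end analysis pipeline: snapshot -> populations -> CVF ->
## adverse events -> resistance -> noninferiority statistics, assembled
## into a single printable report object. Identical inputs and
## configuration always produce identical reports.

#' Pipeline configuration
#'
#' @param snapshot a [snapshot_config()].
#' @param suppression_margin noninferiority margin (percentage points) for
#'   the suppression outcome, applied to the lower CI bound.
#' @param cvf_margin noninferiority margin for confirmed virological
#'   failure, applied to the upper CI bound.
#' @param alpha two-sided significance level for all intervals.
#' @param count_adjudicated_cvf count adjudicated unconfirmed failures as
#'   failures.
#' @param lists a [mutation_lists()] (used when the dataset carries
#'   sequences), or `NULL` for the shipped defaults.
#' @param drugs drugs for which baseline resistance prevalence is reported.
#' @return a `pipeline_config` list.
#' @export
pipeline_config <- function(snapshot = snapshot_config(),
                            suppression_margin = 10,
                            cvf_margin = 4,
                            alpha = 0.05,
                            count_adjudicated_cvf = TRUE,
                            lists = NULL,
                            drugs = "rilpivirine") {
  stopifnot(suppression_margin > 0, cvf_margin > 0, alpha > 0, alpha < 1)
  structure(
    list(snapshot = snapshot, suppression_margin = suppression_margin,
         cvf_margin = cvf_margin, alpha = alpha,
         count_adjudicated_cvf = count_adjudicated_cvf, lists = lists,
         drugs = drugs),
    class = "pipeline_config"
  )
}

arm_counts <- function(tab, col) {
  x1 <- tab[tab$arm == "long_acting", col]
  n1 <- tab[tab$arm == "long_acting", "n"]
  x2 <- tab[tab$arm == "oral", col]
  n2 <- tab[tab$arm == "oral", "n"]
  list(x1 = x1, n1 = n1, x2 = x2, n2 = n2)
}

## per-stratum suppression counts for the CMH-adjusted analysis
stratified_counts <- function(cls, participants) {
  stratum <- participants$stratum[match(cls$participant_id,
                                        participants$participant_id)]
  out <- lapply(STRATUM_LEVELS, function(s) {
    sub <- cls[stratum == s, , drop = FALSE]
    data.frame(
      stratum = s,
      x1 = sum(sub$arm == "long_acting" & sub$category == "suppressed"),
      n1 = sum(sub$arm == "long_acting"),
      x2 = sum(sub$arm == "oral" & sub$category == "suppressed"),
      n2 = sum(sub$arm == "oral"),
      stringsAsFactors = FALSE
    )
  })
  do.call(rbind, out)
}

#' Run the full analysis pipeline
#'
#' Classifies every participant (modified snapshot), derives the analysis
#' populations, detects confirmed virological failure, summarizes adverse
#' events with normal-approximation intervals, computes resistance
#' prevalence with and without the APOBEC filter when sequences are
#' present, and attaches risk-difference intervals and noninferiority
#' decisions: the suppression outcome uses the stratified CMH-weighted
#' score interval against the lower-bound margin, confirmed virological
#' failure the unstratified score interval against the upper-bound margin.
#'
#' @param ds a [trial_dataset()].
#' @param config a [pipeline_config()].
#' @return a `trial_report` object (named list of tables and decisions).
#' @export
run_pipeline <- function(ds, config = pipeline_config()) {
  stopifnot(inherits(ds, "trial_dataset"))
  cls <- snapshot_classify(ds, config$snapshot)
  snap <- snapshot_table(ds, config$snapshot)
  strata <- stratified_counts(cls, ds$participants)
  sc <- arm_counts(snap, "suppressed")

  informative <- strata[strata$n1 > 0 & strata$n2 > 0, , drop = FALSE]
  supp_ci_strat <- if (nrow(informative)) cmh_mn_ci(informative, config$alpha)
  else NULL
  supp_ci_crude <- if (sc$n1 > 0 && sc$n2 > 0) {
    mn_score_ci(sc$x1, sc$n1, sc$x2, sc$n2, config$alpha)
  } else NULL
  supp_decision <- if (!is.null(supp_ci_strat)) {
    noninferiority_decision(supp_ci_strat, config$suppression_margin, "lower")
  } else NULL

  cvf <- cvf_table(ds, config$count_adjudicated_cvf)
  cc <- arm_counts(cvf, "failures")
  cvf_ci <- if (cc$n1 > 0 && cc$n2 > 0) {
    mn_score_ci(cc$x1, cc$n1, cc$x2, cc$n2, config$alpha)
  } else NULL
  cvf_decision <- if (!is.null(cvf_ci)) {
    noninferiority_decision(cvf_ci, config$cvf_margin, "upper")
  } else NULL

  pops <- population_summary(ds, config$snapshot)

  ## adverse-event summary with Wald intervals
  ae <- ds$adverse_events
  n1 <- sum(ds$participants$arm == "long_acting")
  n2 <- sum(ds$participants$arm == "oral")
  ae_count <- function(filter) {
    sub <- ae[filter(ae), , drop = FALSE]
    arm <- ds$participants$arm[match(unique(sub$participant_id),
                                     ds$participants$participant_id)]
    c(sum(arm == "long_acting"), sum(arm == "oral"))
  }
  ae_catalog <- list(
    grade3_any = function(a) a$grade >= 3,
    grade3_related = function(a) a$grade >= 3 & a$related,
    serious_any = function(a) a$serious,
    any_event = function(a) rep(TRUE, nrow(a)),
    discontinuation = function(a) a$led_to_discontinuation,
    injection_site = function(a) a$injection_site
  )
  ae_rows <- lapply(names(ae_catalog), function(nm) {
    cts <- ae_count(ae_catalog[[nm]])
    ci <- if (n1 > 0 && n2 > 0) wald_ci(cts[[1L]], n1, cts[[2L]], n2,
                                        config$alpha) else NULL
    data.frame(category = nm, x1 = cts[[1L]], n1 = n1, x2 = cts[[2L]],
               n2 = n2,
               estimate = if (is.null(ci)) NA_real_ else ci$estimate,
               lower = if (is.null(ci)) NA_real_ else ci$lower,
               upper = if (is.null(ci)) NA_real_ else ci$upper,
               stringsAsFactors = FALSE)
  })
  ae_summary <- do.call(rbind, ae_rows)

  resistance <- NULL
  if (nrow(ds$sequences)) {
    lists <- config$lists %||% mutation_lists()
    resistance <- do.call(rbind, lapply(config$drugs, function(drug) {
      filt <- resistance_prevalence(ds, lists, drug, arm = "long_acting",
                                    apply_filter = TRUE)
      unfilt <- resistance_prevalence(ds, lists, drug, arm = "long_acting",
                                      apply_filter = FALSE)
      data.frame(drug = drug, arm = "long_acting",
                 filtered_numerator = filt$numerator,
                 denominator = filt$denominator,
                 filtered_prevalence = filt$prevalence,
                 unfiltered_numerator = unfilt$numerator,
                 unfiltered_prevalence = unfilt$prevalence,
                 stringsAsFactors = FALSE)
    }))
  }

  structure(
    list(snapshot = snap, snapshot_strata = strata,
         classification = cls,
         suppression_ci = supp_ci_strat,
         suppression_ci_unstratified = supp_ci_crude,
         suppression_decision = supp_decision,
         cvf = cvf, cvf_ci = cvf_ci, cvf_decision = cvf_decision,
         populations = pops, ae_summary = ae_summary,
         resistance = resistance, config = config),
    class = "trial_report"
  )
}

decision_word <- function(d) if (is.null(d)) "n/a" else if (d$met) "met" else "not met"

#' @export
print.trial_report <- function(x, ...) {
  cat("== Week-96 virologic outcome (modified FDA snapshot) ==\n")
  print(x$snapshot, row.names = FALSE)
  if (!is.null(x$suppression_ci)) {
    cat(sprintf("Suppression difference (CMH-MN): %s\n",
                format(x$suppression_ci)))
    cat(sprintf("Noninferiority (margin -%g pp, lower bound): %s\n",
                x$config$suppression_margin,
                decision_word(x$suppression_decision)))
  }
  cat("\n== Confirmed virological failure ==\n")
  print(x$cvf, row.names = FALSE)
  if (!is.null(x$cvf_ci)) {
    cat(sprintf("CVF difference (MN): %s\n", format(x$cvf_ci)))
    cat(sprintf("Noninferiority (margin +%g pp, upper bound): %s\n",
                x$config$cvf_margin, decision_word(x$cvf_decision)))
  }
  cat("\n== Analysis populations ==\n")
  print(x$populations, row.names = FALSE)
  cat("\n== Adverse events (Wald CIs, percentage points) ==\n")
  print(x$ae_summary, row.names = FALSE, digits = 3)
  if (!is.null(x$resistance)) {
    cat("\n== Baseline resistance prevalence (long-acting arm) ==\n")
    print(x$resistance, row.names = FALSE, digits = 3)
  }
  invisible(x)
}
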