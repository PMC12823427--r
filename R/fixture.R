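## Deterministic outcome fixture.
##
## make_fixture() constructs, without any randomness, a dataset whose full
## pipeline outputs (snapshot table, CVF counts, population sizes,
## adverse-event counts, resistance prevalence) equal the counts written in
## the fixture specification. The default specification carries the marginal
## outcome counts of the reference 512-participant trial; any consistent
## set of counts can be supplied instead.

#' Fixture specification for one arm
#'
#' @param n arm size.
#' @param suppressed participants with an in-window viral load below the
#'   threshold (and no assigned failure).
#' @param assigned_failure participants assigned nonsuppressed because of an
#'   earlier switch for virological failure (each is also a confirmed CVF).
#' @param observed_nonsuppressed participants with an observed in-window
#'   viral load at or above the threshold.
#' @param withdrawals,deaths participants with no in-window viral load due
#'   to withdrawal/death before week 96.
#' @param adjudicated_failures deaths that carry an adjudicated unconfirmed
#'   failure (single high viral load, no retest possible).
#' @param pp_delay_gt14 suppressed participants with one injection more than
#'   14 days late without bridging (per-protocol exclusions).
#' @param pp_missed_oral participants who missed more than 7 days of oral
#'   treatment at a visit (per-protocol exclusions).
#' @param pp_missed_nonsuppressed how many of `pp_missed_oral` are among the
#'   observed nonsuppressed (the rest are suppressed participants).
#' @param bridged_delays suppressed participants with a long injection delay
#'   fully covered by oral bridging (retained in per-protocol).
#' @param nonsupp_copies viral-load values (recycled) for the observed
#'   nonsuppressed participants.
#' @param n_insti participants in the INSTI third-drug stratum (the rest
#'   are NNRTI).
#' @param ae named counts of participants with at least one adverse event of
#'   each category: `any`, `grade3`, `serious`, `related_grade3`,
#'   `discontinuation`, `injection_site`.
#' @param seq_n baseline RT sequences in the arm.
#' @param drm_retained sequenced participants carrying a retained
#'   (non-APOBEC-context) rilpivirine mutation, E138A.
#' @param drm_context sequenced participants carrying the APOBEC-context
#'   mutation E138K on a sequence with a signature hypermutation (filtered).
#' @return a validated per-arm specification list.
#' @export
fixture_arm <- function(n, suppressed, assigned_failure = 0L,
                        observed_nonsuppressed = 0L, withdrawals = 0L,
                        deaths = 0L, adjudicated_failures = 0L,
                        pp_delay_gt14 = 0L, pp_missed_oral = 0L,
                        pp_missed_nonsuppressed = 0L, bridged_delays = 0L,
                        nonsupp_copies = 150L, n_insti = NULL,
                        ae = c(any = 0L, grade3 = 0L, serious = 0L,
                               related_grade3 = 0L, discontinuation = 0L,
                               injection_site = 0L),
                        seq_n = 0L, drm_retained = 0L, drm_context = 0L) {
  spec <- list(n = as.integer(n), suppressed = as.integer(suppressed),
               assigned_failure = as.integer(assigned_failure),
               observed_nonsuppressed = as.integer(observed_nonsuppressed),
               withdrawals = as.integer(withdrawals),
               deaths = as.integer(deaths),
               adjudicated_failures = as.integer(adjudicated_failures),
               pp_delay_gt14 = as.integer(pp_delay_gt14),
               pp_missed_oral = as.integer(pp_missed_oral),
               pp_missed_nonsuppressed = as.integer(pp_missed_nonsuppressed),
               bridged_delays = as.integer(bridged_delays),
               nonsupp_copies = as.integer(nonsupp_copies),
               n_insti = as.integer(n_insti %||% n),
               ae = ae, seq_n = as.integer(seq_n),
               drm_retained = as.integer(drm_retained),
               drm_context = as.integer(drm_context))
  total <- spec$suppressed + spec$assigned_failure +
    spec$observed_nonsuppressed + spec$withdrawals + spec$deaths
  if (total != spec$n) {
    vs_stop("virosnap_config_error",
            "fixture arm counts sum to %d, not n = %d", total, spec$n)
  }
  if (spec$adjudicated_failures > spec$deaths) {
    vs_stop("virosnap_config_error",
            "adjudicated failures must be a subset of deaths")
  }
  if (spec$pp_missed_nonsuppressed > min(spec$pp_missed_oral,
                                         spec$observed_nonsuppressed)) {
    vs_stop("virosnap_config_error",
            "pp_missed_nonsuppressed exceeds available participants")
  }
  supp_roles <- spec$pp_delay_gt14 +
    (spec$pp_missed_oral - spec$pp_missed_nonsuppressed) + spec$bridged_delays
  if (supp_roles > spec$suppressed) {
    vs_stop("virosnap_config_error",
            "per-protocol role counts exceed the suppressed count")
  }
  if (spec$n_insti > spec$n) {
    vs_stop("virosnap_config_error", "n_insti exceeds n")
  }
  if (spec$drm_retained + spec$drm_context > spec$seq_n) {
    vs_stop("virosnap_config_error", "resistance counts exceed seq_n")
  }
  spec
}

#' Full fixture specification (both arms)
#'
#' The default reproduces the reference trial's marginal counts: snapshot
#' 247/4/4 vs 250/2/5 (suppressed/nonsuppressed/no-data), CVF 4 vs 0
#' (one adjudicated), per-protocol sizes 224 (255 - 4 - 22 - 5) and
#' 215 (257 - 5 - 37), complete-case sizes 251 and 252, the Table of
#' adverse-event counts, and baseline rilpivirine-resistance prevalence
#' 14/208 filtered (25/208 unfiltered) in the long-acting arm.
#'
#' @param long_acting,oral per-arm specifications from [fixture_arm()].
#' @return a `fixture_spec` list.
#' @export
fixture_spec <- function(
    long_acting = fixture_arm(
      n = 255, suppressed = 247, assigned_failure = 3,
      observed_nonsuppressed = 1, withdrawals = 3, deaths = 1,
      adjudicated_failures = 1, pp_delay_gt14 = 22, pp_missed_oral = 5,
      bridged_delays = 2, n_insti = 231,
      ae = c(any = 230, grade3 = 41, serious = 12, related_grade3 = 5,
             discontinuation = 2, injection_site = 197),
      seq_n = 208, drm_retained = 14, drm_context = 11),
    oral = fixture_arm(
      n = 257, suppressed = 250, observed_nonsuppressed = 2,
      withdrawals = 4, deaths = 1, pp_missed_oral = 37,
      pp_missed_nonsuppressed = 1, nonsupp_copies = c(150L, 600L),
      n_insti = 240,
      ae = c(any = 185, grade3 = 22, serious = 9, related_grade3 = 4,
             discontinuation = 5, injection_site = 0),
      seq_n = 193, drm_retained = 16, drm_context = 8)) {
  structure(list(long_acting = long_acting, oral = oral),
            class = "fixture_spec")
}

## viral-load trajectories for the confirmed failures, recycled in order
FAILURE_TRAJECTORIES <- list(
  list(week = 48L, values = c(8608L, 16124L)),
  list(week = 72L, values = c(798L, 563L)),
  list(week = 72L, values = c(259L, 16161L))
)
ADJUDICATED_VALUE <- 44984L
ADJUDICATED_WEEK <- 48L

#' Build the deterministic fixture dataset
#'
#' Constructs a [trial_dataset()] whose pipeline outputs reproduce the
#' counts in `spec` exactly; the construction involves no random draws.
#'
#' @param spec a [fixture_spec()].
#' @return a `trial_dataset`.
#' @export
make_fixture <- function(spec = fixture_spec()) {
  stopifnot(inherits(spec, "fixture_spec"))
  parts <- list()
  for (a in ARM_LEVELS) {
    s <- spec[[a]]
    if (s$n > 0) {
      parts[[a]] <- build_fixture_arm(a, s,
                                      prefix = if (a == "long_acting") "LA"
                                      else "OR")
    }
  }
  combine <- function(name) {
    tabs <- lapply(parts, `[[`, name)
    tabs <- tabs[!vapply(tabs, is.null, logical(1))]
    if (!length(tabs)) return(empty_table(name))
    do.call(rbind, tabs)
  }
  trial_dataset(
    participants = combine("participants"),
    viral_loads = combine("viral_loads"),
    doses = combine("doses"),
    regimen_changes = combine("regimen_changes"),
    adverse_events = combine("adverse_events"),
    sequences = combine("sequences"),
    mutation_calls = combine("mutation_calls")
  )
}

build_fixture_arm <- function(arm, s, prefix) {
  n <- s$n
  ids <- sprintf("%s%04d", prefix, seq_len(n))
  ## role index ranges, in order
  i_assigned <- seq_len(s$assigned_failure)
  i_adj <- seq_len(s$adjudicated_failures) + s$assigned_failure
  i_nonsupp <- seq_len(s$observed_nonsuppressed) + s$assigned_failure +
    s$adjudicated_failures
  after_ns <- s$assigned_failure + s$adjudicated_failures +
    s$observed_nonsuppressed
  i_withdraw <- seq_len(s$withdrawals) + after_ns
  i_death <- seq_len(s$deaths - s$adjudicated_failures) + after_ns +
    s$withdrawals
  first_supp <- after_ns + s$withdrawals + (s$deaths - s$adjudicated_failures)
  i_delay <- seq_len(s$pp_delay_gt14) + first_supp
  n_missed_supp <- s$pp_missed_oral - s$pp_missed_nonsuppressed
  i_missed <- seq_len(n_missed_supp) + first_supp + s$pp_delay_gt14
  i_bridged <- seq_len(s$bridged_delays) + first_supp + s$pp_delay_gt14 +
    n_missed_supp
  ## nonsuppressed participants who also missed oral treatment
  i_missed_ns <- i_nonsupp[seq_len(s$pp_missed_nonsuppressed)]

  withdrawal_day <- rep(NA_integer_, n)
  death_day <- rep(NA_integer_, n)
  adjudicated_day <- rep(NA_integer_, n)
  adjudication_note <- rep(NA_character_, n)
  withdrawal_day[i_withdraw] <- 540L + 2L * seq_along(i_withdraw)
  death_day[i_death] <- 600L + 2L * seq_along(i_death)
  if (length(i_adj)) {
    death_day[i_adj] <- week_to_day(ADJUDICATED_WEEK) + 9L
    adjudicated_day[i_adj] <- week_to_day(ADJUDICATED_WEEK)
    adjudication_note[i_adj] <-
      "died before retest; viremia judged to preclude resuppression"
  }
  term_day <- pmin(ifelse(is.na(withdrawal_day), Inf, withdrawal_day),
                   ifelse(is.na(death_day), Inf, death_day))

  participants <- data.frame(
    participant_id = ids, arm = arm,
    stratum = c(rep("INSTI", s$n_insti), rep("NNRTI", n - s$n_insti)),
    randomization_day = 0L, withdrawal_day = withdrawal_day,
    death_day = death_day,
    oral_lead_in = arm == "long_acting", sex = rep(c("female", "male"),
                                                   length.out = n),
    baseline_bmi = 25.5, adjudicated_failure_day = adjudicated_day,
    adjudication_note = adjudication_note, stringsAsFactors = FALSE
  )

  ## viral loads ------------------------------------------------------
  vl_pid <- list(); vl_day <- list(); vl_copies <- list(); vl_lloq <- list()
  change <- list()
  nonsupp_values <- rep(s$nonsupp_copies, length.out = max(1L,
                                                           length(i_nonsupp)))
  sched_days <- week_to_day(VL_WEEKS)
  for (i in seq_len(n)) {
    days <- sched_days[sched_days < term_day[[i]]]
    copies <- rep(0L, length(days))
    lloq <- rep(TRUE, length(days))
    if (i %in% i_assigned) {
      traj <- FAILURE_TRAJECTORIES[[(match(i, i_assigned) - 1L) %%
                                      length(FAILURE_TRAJECTORIES) + 1L]]
      f_day <- week_to_day(traj$week)
      k <- match(f_day, days)
      copies[[k]] <- traj$values[[1L]]
      lloq[[k]] <- FALSE
      retest_day <- f_day + 35L  # inside the 4-6 week retest window
      days <- append(days, retest_day, after = k)
      copies <- append(copies, traj$values[[2L]], after = k)
      lloq <- append(lloq, FALSE, after = k)
      change[[length(change) + 1L]] <- data.frame(
        participant_id = ids[[i]], start_day = retest_day + 14L,
        end_day = NA_integer_, within_class = FALSE,
        reason = "virological_failure", to_long_acting_oral_forms = FALSE,
        stringsAsFactors = FALSE)
    } else if (i %in% i_adj) {
      k <- match(week_to_day(ADJUDICATED_WEEK), days)
      copies[[k]] <- ADJUDICATED_VALUE
      lloq[[k]] <- FALSE
    } else if (i %in% i_nonsupp) {
      k <- match(week_to_day(96L), days)
      copies[[k]] <- nonsupp_values[[match(i, i_nonsupp)]]
      lloq[[k]] <- FALSE
    }
    vl_pid[[i]] <- rep(ids[[i]], length(days))
    vl_day[[i]] <- days
    vl_copies[[i]] <- copies
    vl_lloq[[i]] <- lloq
  }
  viral_loads <- data.frame(
    participant_id = unlist(vl_pid), study_day = as.integer(unlist(vl_day)),
    nominal_week = as.integer(round(unlist(vl_day) / 7)),
    copies_per_ml = as.integer(unlist(vl_copies)),
    below_lloq = unlist(vl_lloq), stringsAsFactors = FALSE
  )

  ## doses ------------------------------------------------------------
  switch_days <- rep(Inf, n)
  for (ch in change) {
    switch_days[match(ch$participant_id, ids)] <- ch$start_day
  }
  d_pid <- list(); d_kind <- list(); d_target <- list(); d_actual <- list()
  d_missed <- list(); d_bs <- list(); d_be <- list()
  push <- function(p, k, t, a, m, bs, be) {
    j <- length(d_pid) + 1L
    d_pid[[j]] <<- p; d_kind[[j]] <<- k; d_target[[j]] <<- t
    d_actual[[j]] <<- a; d_missed[[j]] <<- m; d_bs[[j]] <<- bs; d_be[[j]] <<- be
  }
  delay_target <- week_to_day(56L)  # the injection that is given late
  for (i in seq_len(n)) {
    if (arm == "long_acting") {
      lead_missed <- if (i %in% i_missed) 10L else 0L
      push(ids[[i]], "oral_dispense", 0L, 0L, lead_missed, NA_integer_,
           NA_integer_)
      targets <- week_to_day(INJECTION_WEEKS)
      targets <- targets[targets < pmin(term_day[[i]], switch_days[[i]])]
      m <- length(targets)
      if (m) {
        actual <- targets
        if (i %in% i_delay && delay_target %in% targets) {
          actual[match(delay_target, targets)] <- delay_target + 20L
        }
        if (i %in% i_bridged && delay_target %in% targets) {
          actual[match(delay_target, targets)] <- delay_target + 21L
          push(ids[[i]], "oral_bridge", delay_target, delay_target, 0L,
               delay_target, delay_target + 21L)
        }
        push(rep(ids[[i]], m), rep("injection", m), targets, actual,
             rep(0L, m), rep(NA_integer_, m), rep(NA_integer_, m))
      }
    } else {
      targets <- c(0L, week_to_day(ORAL_DISPENSE_WEEKS))
      targets <- targets[targets < term_day[[i]]]
      missed <- rep(0L, length(targets))
      if ((i %in% i_missed || i %in% i_missed_ns) && length(targets) >= 3L) {
        missed[[3L]] <- 10L  # the week-24 dispensing visit
      }
      push(rep(ids[[i]], length(targets)), rep("oral_dispense",
                                               length(targets)),
           targets, targets, missed, rep(NA_integer_, length(targets)),
           rep(NA_integer_, length(targets)))
    }
  }
  doses <- data.frame(
    participant_id = unlist(d_pid), kind = unlist(d_kind),
    target_day = as.integer(unlist(d_target)),
    actual_day = as.integer(unlist(d_actual)),
    missed_oral_days = as.integer(unlist(d_missed)),
    bridge_start_day = as.integer(unlist(d_bs)),
    bridge_end_day = as.integer(unlist(d_be)), stringsAsFactors = FALSE
  )

  ## adverse events ----------------------------------------------------
  ae_rows <- list()
  ae_push <- function(count, grade, serious = FALSE, related = FALSE,
                      injection_site = FALSE, disc = FALSE) {
    if (count <= 0) return(invisible(NULL))
    sel <- seq_len(count)
    ae_rows[[length(ae_rows) + 1L]] <<- data.frame(
      participant_id = ids[sel], onset_day = 100L + (sel %% 400L),
      grade = as.integer(grade), serious = serious, related = related,
      injection_site = injection_site, led_to_discontinuation = disc,
      stringsAsFactors = FALSE)
  }
  ae_push(s$ae[["any"]], grade = 1L)
  ae_push(s$ae[["grade3"]], grade = 3L)
  ae_push(s$ae[["serious"]], grade = 3L, serious = TRUE)
  ae_push(s$ae[["related_grade3"]], grade = 3L, related = TRUE)
  ae_push(s$ae[["discontinuation"]], grade = 3L, disc = TRUE)
  ae_push(s$ae[["injection_site"]], grade = 1L, injection_site = TRUE)
  adverse_events <- if (length(ae_rows)) do.call(rbind, ae_rows)
  else empty_table("adverse_events")

  ## baseline sequences and mutation calls -----------------------------
  sequences <- empty_table("sequences")
  mutation_calls <- empty_table("mutation_calls")
  if (s$seq_n > 0) {
    lists <- mutation_lists()
    ref <- ref_residues("RT", lists)
    wt <- paste(ref, collapse = "")
    retained_res <- paste(set_residue(ref, 138L, "A"), collapse = "")
    sig <- lists$signatures[lists$signatures$gene == "RT", , drop = FALSE]
    ctx_res <- set_residue(ref, 138L, "K")
    ctx_res <- set_residue(ctx_res, sig$position[[1L]], sig$aa[[1L]])
    ctx_res <- paste(ctx_res, collapse = "")
    ## resistance roles start after the disposition/PP roles where possible
    start <- min(first_supp + s$pp_delay_gt14 + n_missed_supp +
                   s$bridged_delays, n - s$seq_n) + 1L
    start <- max(1L, min(start, n - s$seq_n + 1L))
    i_seq <- seq(start, length.out = s$seq_n)
    i_ret <- i_seq[seq_len(s$drm_retained)]
    i_ctx <- i_seq[seq_len(s$drm_context) + s$drm_retained]
    residues <- rep(wt, s$seq_n)
    residues[match(i_ret, i_seq)] <- retained_res
    residues[match(i_ctx, i_seq)] <- ctx_res
    sequences <- data.frame(
      participant_id = ids[i_seq], timepoint = "baseline", gene = "RT",
      residues = residues, stringsAsFactors = FALSE)
    drm_ids <- c(ids[i_ret], ids[i_ctx])
    if (length(drm_ids)) {
      mutation_calls <- data.frame(
        participant_id = drm_ids, timepoint = "baseline", gene = "RT",
        mutation = c(rep("E138A", length(i_ret)), rep("E138K",
                                                      length(i_ctx))),
        stringsAsFactors = FALSE)
    }
  }

  list(participants = participants, viral_loads = viral_loads,
       doses = doses,
       regimen_changes = if (length(change)) do.call(rbind, change)
       else empty_table("regimen_changes"),
       adverse_events = adverse_events, sequences = sequences,
       mutation_calls = mutation_calls)
}
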