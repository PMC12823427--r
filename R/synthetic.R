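## Seeded synthetic-trial generator.
##
## Emulates the design the analysis assumes: 1:1 randomization by permuted
## blocks stratified by third-drug class; long-acting-arm visits at weeks 4
## and 8 then 8-weekly to week 96, oral-arm visits at week 12 then 12-weekly;
## viral loads every 24 weeks with rare rebound; retest visits generated by
## the monitoring rules themselves; injection delays with optional oral
## bridging; missed-oral-dose streaks; withdrawals and deaths; graded
## adverse events; and baseline sequences carrying resistance mutations with
## or without APOBEC evidence. Default parameter values are calibrated to
## the marginal frequencies reported for a 512-participant switch trial of
## this design (97% week-96 suppression, ~1.6% cumulative failure risk in
## the long-acting arm, 10% of participants with a >14-day injection delay,
## 14% with a missed-oral streak, ~1.8% withdrawal/death).

INJECTION_WEEKS <- c(4L, 8L, seq(16L, 96L, by = 8L))
ORAL_DISPENSE_WEEKS <- seq(12L, 96L, by = 12L)
VL_WEEKS <- seq(0L, 96L, by = 24L)
AA20 <- strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1L]]
GENE_LENGTHS <- c(RT = 240L, IN = 288L)

## deterministic pseudo-reference residue string for a gene, guaranteed not
## to carry any signature mutation from `lists`
ref_residues <- function(gene, lists) {
  len <- GENE_LENGTHS[[gene]]
  res <- AA20[(seq_len(len) - 1L) %% 20L + 1L]
  sig <- lists$signatures[lists$signatures$gene == gene, , drop = FALSE]
  for (i in seq_len(nrow(sig))) {
    p <- sig$position[[i]]
    if (p <= len && res[[p]] == sig$aa[[i]]) {
      res[[p]] <- AA20[(match(res[[p]], AA20)) %% 20L + 1L]
    }
  }
  res
}

set_residue <- function(res, position, aa) {
  res[[position]] <- aa
  res
}

#' Simulation settings for the synthetic trial generator
#'
#' All probabilities are per the event described; see argument list. The
#' defaults define the reference study conditions; the `seed` has no
#' default so that every generated dataset is explicitly reproducible.
#'
#' @param seed integer RNG seed (required).
#' @param n_total total participants across both arms (1:1 allocation).
#' @param block_size permuted-block size (even).
#' @param stratum_probability probability of the NNRTI third-drug stratum.
#' @param p_suppress named per-arm probability that a participant who
#'   reaches week 96 without rebound has a week-96 viral load below 50.
#' @param cvf_hazard named per-arm per-visit probability of viral rebound to
#'   >= 200 copies/ml at each post-baseline scheduled viral-load visit.
#' @param rebound_log10_mean,rebound_log10_sd lognormal (base-10) magnitude
#'   of rebound viral loads.
#' @param delay_probs probabilities of an injection delay of 0, 1-7, 8-14,
#'   >= 15 days (must sum to 1).
#' @param p_bridge probability a >= 15-day delay is covered by oral bridging.
#' @param withdrawal_prob,death_prob per-participant probabilities of
#'   withdrawal/death before week 96.
#' @param p_oral_lead_in probability a long-acting participant takes the
#'   4-week oral lead-in.
#' @param missed_oral_probs probabilities of 0, 1-7, > 7 missed oral days at
#'   a dispensing visit (must sum to 1).
#' @param ae_rates per-arm list of adverse-event rates: `any`, `grade3`,
#'   `serious`, `related_grade3`, `discontinuation`, `injection_site`.
#' @param p_sequence probability a participant has a baseline RT sequence.
#' @param p_baseline_drm probability that a sequenced participant carries a
#'   rilpivirine resistance mutation call.
#' @param p_apobec_evidence probability that such a mutation is an
#'   APOBEC-context mutation on a sequence with APOBEC evidence (and hence
#'   filtered).
#' @return a validated `sim_config` list.
#' @export
sim_config <- function(seed,
                       n_total = 512L,
                       block_size = 4L,
                       stratum_probability = 0.08,
                       p_suppress = c(long_acting = 0.97, oral = 0.97),
                       cvf_hazard = c(long_acting = 0.004, oral = 0),
                       rebound_log10_mean = 3.5,
                       rebound_log10_sd = 0.8,
                       delay_probs = c(0.85, 0.10, 0.042, 0.008),
                       p_bridge = 0.10,
                       withdrawal_prob = 0.014,
                       death_prob = 0.004,
                       p_oral_lead_in = 0.84,
                       missed_oral_probs = c(0.83, 0.151, 0.019),
                       ae_rates = list(
                         long_acting = c(any = 0.90, grade3 = 0.16,
                                         serious = 0.047, related_grade3 = 0.02,
                                         discontinuation = 0.008,
                                         injection_site = 0.77),
                         oral = c(any = 0.72, grade3 = 0.086,
                                  serious = 0.035, related_grade3 = 0.016,
                                  discontinuation = 0.019,
                                  injection_site = 0)
                       ),
                       p_sequence = 0.8,
                       p_baseline_drm = 0.12,
                       p_apobec_evidence = 0.4) {
  if (missing(seed) || is.null(seed) || is.na(seed)) {
    vs_stop("virosnap_config_error",
            "an explicit integer seed is required for reproducibility")
  }
  probs <- c(stratum_probability, p_suppress, cvf_hazard, delay_probs,
             p_bridge, withdrawal_prob, death_prob, p_oral_lead_in,
             missed_oral_probs, unlist(ae_rates), p_sequence,
             p_baseline_drm, p_apobec_evidence)
  if (any(probs < 0 | probs > 1)) {
    vs_stop("virosnap_config_error", "all probabilities must lie in [0, 1]")
  }
  if (abs(sum(delay_probs) - 1) > 1e-8 || abs(sum(missed_oral_probs) - 1) > 1e-8) {
    vs_stop("virosnap_config_error",
            "delay_probs and missed_oral_probs must each sum to 1")
  }
  if (n_total < 2) vs_stop("virosnap_config_error", "n_total must be >= 2")
  if (block_size %% 2 != 0 || block_size < 2) {
    vs_stop("virosnap_config_error", "block_size must be a positive even number")
  }
  structure(
    list(seed = as.integer(seed), n_total = as.integer(n_total),
         block_size = as.integer(block_size),
         stratum_probability = stratum_probability,
         p_suppress = p_suppress, cvf_hazard = cvf_hazard,
         rebound_log10_mean = rebound_log10_mean,
         rebound_log10_sd = rebound_log10_sd,
         delay_probs = delay_probs, p_bridge = p_bridge,
         withdrawal_prob = withdrawal_prob, death_prob = death_prob,
         p_oral_lead_in = p_oral_lead_in,
         missed_oral_probs = missed_oral_probs,
         ae_rates = ae_rates, p_sequence = p_sequence,
         p_baseline_drm = p_baseline_drm,
         p_apobec_evidence = p_apobec_evidence),
    class = "sim_config"
  )
}

## permuted-block allocation within one stratum; balanced to +/- block/2
permuted_block_arms <- function(n, block_size) {
  n_blocks <- ceiling(n / block_size)
  arms <- unlist(lapply(seq_len(n_blocks), function(b) {
    sample(rep(ARM_LEVELS, block_size / 2L))
  }))
  arms[seq_len(n)]
}

rebound_value <- function(config, floor_value = 200) {
  v <- round(10^stats::rnorm(1, config$rebound_log10_mean,
                             config$rebound_log10_sd))
  as.integer(max(floor_value, v))
}

#' Generate a synthetic trial dataset
#'
#' Draws a complete participant-level dataset under the study conditions in
#' `config`. The same seed always yields an identical dataset; retest
#' visits are created by applying [retest_due()] to the simulated series, so
#' the generator and the failure detector agree by construction; once a
#' participant rebounds, viral loads stay at or above 200 copies/ml until a
#' simulated switch to standard oral therapy, after which they resuppress.
#'
#' @param config a [sim_config()].
#' @return a [trial_dataset()].
#' @export
generate_trial <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  with_seed(config$seed, generate_trial_impl(config))
}

generate_trial_impl <- function(config) {
  n <- config$n_total
  ids <- sprintf("P%05d", seq_len(n))
  stratum <- ifelse(stats::runif(n) < config$stratum_probability,
                    "NNRTI", "INSTI")
  arm <- character(n)
  for (s in STRATUM_LEVELS) {
    idx <- which(stratum == s)
    if (length(idx)) arm[idx] <- permuted_block_arms(length(idx),
                                                    config$block_size)
  }

  withdrawal_day <- rep(NA_integer_, n)
  death_day <- rep(NA_integer_, n)
  wd <- stats::runif(n) < config$withdrawal_prob
  withdrawal_day[wd] <- as.integer(sample(30:660, sum(wd), replace = TRUE))
  dd <- stats::runif(n) < config$death_prob
  death_day[dd] <- as.integer(sample(30:660, sum(dd), replace = TRUE))
  ## the earlier disposition event governs; drop the later one
  both <- !is.na(withdrawal_day) & !is.na(death_day)
  drop_w <- both & death_day <= withdrawal_day
  withdrawal_day[drop_w] <- NA_integer_
  death_day[both & !drop_w] <- NA_integer_
  term_day <- pmin(ifelse(is.na(withdrawal_day), Inf, withdrawal_day),
                   ifelse(is.na(death_day), Inf, death_day))

  oral_lead_in <- arm == "long_acting" &
    stats::runif(n) < config$p_oral_lead_in
  sex <- ifelse(stats::runif(n) < 0.58, "female", "male")
  bmi <- round(pmax(16, stats::rnorm(n, 25.5, 4.5)), 1)

  ## rebound week per participant (first success over post-baseline visits)
  hazard <- unname(config$cvf_hazard[arm])
  visit_weeks <- VL_WEEKS[-1L]
  rebound_week <- rep(NA_integer_, n)
  draws <- matrix(stats::runif(n * length(visit_weeks)), nrow = n)
  for (j in seq_along(visit_weeks)) {
    hit <- is.na(rebound_week) & draws[, j] < hazard
    rebound_week[hit] <- visit_weeks[[j]]
  }
  idx_trunc <- which(!is.na(rebound_week) &
                       week_to_day(rebound_week) >= term_day)
  rebound_week[idx_trunc] <- NA_integer_

  blip <- stats::runif(n) >= unname(config$p_suppress[arm])

  acc_pid <- vector("list", n)
  acc_day <- vector("list", n)
  acc_week <- vector("list", n)
  acc_copies <- vector("list", n)
  acc_lloq <- vector("list", n)
  change_rows <- vector("list", n)
  adjudicated_failure_day <- rep(NA_integer_, n)

  for (i in seq_len(n)) {
    weeks <- VL_WEEKS[week_to_day(VL_WEEKS) < term_day[[i]]]
    days <- week_to_day(weeks)
    copies <- rep(0L, length(weeks))
    lloq <- rep(TRUE, length(weeks))
    rw <- rebound_week[[i]]
    if (!is.na(rw) && rw %in% weeks) {
      rule <- monitoring_rule(arm[[i]])
      r_idx <- match(rw, weeks)
      r_day <- days[[r_idx]]
      v1 <- rebound_value(config)
      copies[[r_idx]] <- v1
      lloq[[r_idx]] <- FALSE
      win <- retest_due(r_day, v1, FALSE, rule)
      switch_day <- NA_integer_
      if (!is.null(win)) {
        retest_day <- as.integer(round(mean(win)))
        if (retest_day < term_day[[i]]) {
          v2 <- rebound_value(config)
          days <- c(days, retest_day)
          weeks <- c(weeks, as.integer(round(retest_day / 7)))
          copies <- c(copies, v2)
          lloq <- c(lloq, FALSE)
          switch_day <- retest_day + 14L
          change_rows[[i]] <- data.frame(
            participant_id = ids[[i]], start_day = switch_day,
            end_day = NA_integer_, within_class = FALSE,
            reason = "virological_failure",
            to_long_acting_oral_forms = FALSE, stringsAsFactors = FALSE)
        }
      }
      ## later scheduled values: high until switch, resuppressed after
      for (k in which(days > r_day)) {
        if (!lloq[[k]]) next                              # the retest row
        if (!is.na(switch_day) && days[[k]] > switch_day) next  # resuppressed
        copies[[k]] <- rebound_value(config)
        lloq[[k]] <- FALSE
      }
      ## re-sort by day (retest row may precede a scheduled visit)
      ord <- order(days)
      days <- days[ord]; weeks <- weeks[ord]
      copies <- copies[ord]; lloq <- lloq[ord]
    } else if (blip[[i]] && 96L %in% weeks) {
      k <- match(96L, weeks)
      copies[[k]] <- as.integer(50 + floor(stats::runif(1) * 150))
      lloq[[k]] <- FALSE
    }
    acc_pid[[i]] <- rep(ids[[i]], length(days))
    acc_day[[i]] <- days
    acc_week[[i]] <- weeks
    acc_copies[[i]] <- copies
    acc_lloq[[i]] <- lloq
  }
  viral_loads <- data.frame(
    participant_id = unlist(acc_pid), study_day = as.integer(unlist(acc_day)),
    nominal_week = as.integer(unlist(acc_week)),
    copies_per_ml = as.integer(unlist(acc_copies)),
    below_lloq = unlist(acc_lloq), stringsAsFactors = FALSE
  )

  doses <- generate_doses(config, ids, arm, oral_lead_in, term_day,
                          change_rows)
  adverse_events <- generate_aes(config, ids, arm, term_day)
  seqres <- generate_sequences(config, ids, arm)

  participants <- data.frame(
    participant_id = ids, arm = arm, stratum = stratum,
    randomization_day = 0L, withdrawal_day = withdrawal_day,
    death_day = death_day, oral_lead_in = oral_lead_in, sex = sex,
    baseline_bmi = bmi, adjudicated_failure_day = adjudicated_failure_day,
    adjudication_note = NA_character_, stringsAsFactors = FALSE
  )
  changes <- do.call(rbind, change_rows[!vapply(change_rows, is.null,
                                                logical(1))])
  trial_dataset(
    participants = participants,
    viral_loads = viral_loads,
    doses = doses,
    regimen_changes = changes %||% empty_table("regimen_changes"),
    adverse_events = adverse_events,
    sequences = seqres$sequences,
    mutation_calls = seqres$mutation_calls
  )
}

## sample missed-oral-day streaks for `m` dispensing visits
sample_missed <- function(m, missed_cut) {
  u <- stats::runif(m)
  out <- integer(m)
  mid <- u >= missed_cut[[1L]] & u < missed_cut[[2L]]
  long <- u >= missed_cut[[2L]]
  if (any(mid)) out[mid] <- as.integer(sample(1:7, sum(mid), replace = TRUE))
  if (any(long)) out[long] <- as.integer(sample(8:14, sum(long),
                                                replace = TRUE))
  out
}

generate_doses <- function(config, ids, arm, oral_lead_in, term_day,
                           change_rows) {
  n <- length(ids)
  delay_cut <- cumsum(config$delay_probs)
  missed_cut <- cumsum(config$missed_oral_probs)
  pid <- list(); kind <- list(); target <- list(); actual <- list()
  missed <- list(); bstart <- list(); bend <- list()
  push <- function(p, k, t, a, m, bs, be) {
    i <- length(pid) + 1L
    pid[[i]] <<- p; kind[[i]] <<- k; target[[i]] <<- t; actual[[i]] <<- a
    missed[[i]] <<- m; bstart[[i]] <<- bs; bend[[i]] <<- be
  }
  for (i in seq_len(n)) {
    if (arm[[i]] == "long_acting") {
      switch_day <- if (!is.null(change_rows[[i]])) {
        change_rows[[i]]$start_day[[1L]]
      } else Inf
      if (oral_lead_in[[i]]) {
        push(ids[[i]], "oral_dispense", 0L, 0L,
             sample_missed(1L, missed_cut), NA_integer_, NA_integer_)
      }
      targets <- week_to_day(INJECTION_WEEKS)
      targets <- targets[targets < pmin(term_day[[i]], switch_day)]
      m <- length(targets)
      if (m) {
        u <- stats::runif(m)
        delay <- integer(m)
        d1 <- u >= delay_cut[[1L]] & u < delay_cut[[2L]]
        d2 <- u >= delay_cut[[2L]] & u < delay_cut[[3L]]
        d3 <- u >= delay_cut[[3L]]
        if (any(d1)) delay[d1] <- as.integer(sample(1:7, sum(d1),
                                                    replace = TRUE))
        if (any(d2)) delay[d2] <- as.integer(sample(8:14, sum(d2),
                                                    replace = TRUE))
        if (any(d3)) delay[d3] <- as.integer(sample(15:28, sum(d3),
                                                    replace = TRUE))
        push(rep(ids[[i]], m), rep("injection", m), targets, targets + delay,
             rep(0L, m), rep(NA_integer_, m), rep(NA_integer_, m))
        for (j in which(d3)) {
          if (stats::runif(1) < config$p_bridge) {
            push(ids[[i]], "oral_bridge", targets[[j]], targets[[j]], 0L,
                 targets[[j]], targets[[j]] + delay[[j]])
          }
        }
      }
    } else {
      targets <- c(0L, week_to_day(ORAL_DISPENSE_WEEKS))
      targets <- targets[targets < term_day[[i]]]
      m <- length(targets)
      if (m) {
        push(rep(ids[[i]], m), rep("oral_dispense", m), targets, targets,
             sample_missed(m, missed_cut), rep(NA_integer_, m),
             rep(NA_integer_, m))
      }
    }
  }
  data.frame(
    participant_id = unlist(pid), kind = unlist(kind),
    target_day = as.integer(unlist(target)),
    actual_day = as.integer(unlist(actual)),
    missed_oral_days = as.integer(unlist(missed)),
    bridge_start_day = as.integer(unlist(bstart)),
    bridge_end_day = as.integer(unlist(bend)), stringsAsFactors = FALSE
  )
}

generate_aes <- function(config, ids, arm, term_day) {
  n <- length(ids)
  out <- list()
  onset <- function(m) as.integer(sample(7:650, m, replace = TRUE))
  for (a in ARM_LEVELS) {
    idx <- which(arm == a)
    r <- config$ae_rates[[a]]
    mk <- function(sel, grade, serious = FALSE, related = FALSE,
                   injection_site = FALSE, disc = FALSE) {
      if (!length(sel)) return(NULL)
      data.frame(participant_id = ids[sel], onset_day = onset(length(sel)),
                 grade = as.integer(grade), serious = serious,
                 related = related, injection_site = injection_site,
                 led_to_discontinuation = disc, stringsAsFactors = FALSE)
    }
    out[[length(out) + 1L]] <- mk(idx[stats::runif(length(idx)) < r[["any"]]],
                                  grade = 1L)
    g3 <- idx[stats::runif(length(idx)) < r[["grade3"]]]
    out[[length(out) + 1L]] <- mk(g3, grade = 3L)
    out[[length(out) + 1L]] <- mk(
      idx[stats::runif(length(idx)) < r[["serious"]]], grade = 3L,
      serious = TRUE)
    out[[length(out) + 1L]] <- mk(
      idx[stats::runif(length(idx)) < r[["related_grade3"]]], grade = 3L,
      related = TRUE)
    out[[length(out) + 1L]] <- mk(
      idx[stats::runif(length(idx)) < r[["discontinuation"]]], grade = 3L,
      disc = TRUE)
    if (r[["injection_site"]] > 0) {
      out[[length(out) + 1L]] <- mk(
        idx[stats::runif(length(idx)) < r[["injection_site"]]], grade = 1L,
        injection_site = TRUE)
    }
  }
  rows <- do.call(rbind, out[!vapply(out, is.null, logical(1))])
  if (is.null(rows)) return(empty_table("adverse_events"))
  rows
}

generate_sequences <- function(config, ids, arm) {
  lists <- mutation_lists()
  ref <- ref_residues("RT", lists)
  n <- length(ids)
  has_seq <- stats::runif(n) < config$p_sequence
  has_drm <- has_seq & stats::runif(n) < config$p_baseline_drm
  apobec <- has_drm & stats::runif(n) < config$p_apobec_evidence
  seq_rows <- list()
  call_rows <- list()
  sig_rt <- lists$signatures[lists$signatures$gene == "RT", , drop = FALSE]
  for (i in which(has_seq)) {
    res <- ref
    if (has_drm[[i]]) {
      if (apobec[[i]]) {
        res <- set_residue(res, 138L, "K")
        sig <- sig_rt[sample(nrow(sig_rt), 1L), , drop = FALSE]
        res <- set_residue(res, sig$position[[1L]], sig$aa[[1L]])
        mut <- "E138K"
      } else {
        res <- set_residue(res, 138L, "A")
        mut <- "E138A"
      }
      call_rows[[length(call_rows) + 1L]] <- data.frame(
        participant_id = ids[[i]], timepoint = "baseline", gene = "RT",
        mutation = mut, stringsAsFactors = FALSE)
    }
    seq_rows[[length(seq_rows) + 1L]] <- data.frame(
      participant_id = ids[[i]], timepoint = "baseline", gene = "RT",
      residues = paste(res, collapse = ""), stringsAsFactors = FALSE)
  }
  list(
    sequences = if (length(seq_rows)) do.call(rbind, seq_rows)
    else empty_table("sequences"),
    mutation_calls = if (length(call_rows)) do.call(rbind, call_rows)
    else empty_table("mutation_calls")
  )
}
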