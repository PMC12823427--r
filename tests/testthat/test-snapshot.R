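change_row <- function(pid = "T001", start, end = NA_integer_,
                       within_class = FALSE, reason = "other",
                       bridge = FALSE) {
  data.frame(participant_id = pid, start_day = as.integer(start),
             end_day = as.integer(end), within_class = within_class,
             reason = reason, to_long_acting_oral_forms = bridge,
             stringsAsFactors = FALSE)
}

test_that("switch rules exempt within-class, bridging and temporary changes", {
  cfg <- snapshot_config()
  ## oral-arm within-class change (e.g. tenofovir -> abacavir)
  res <- is_disqualifying_switch(
    change_row(start = 300, within_class = TRUE, reason = "adverse_event"),
    arm = "oral", config = cfg)
  expect_false(res$disqualifying)

  ## long-acting participant bridged days 400-456, injections resumed
  res <- is_disqualifying_switch(
    change_row(start = 400, end = 456, bridge = TRUE),
    arm = "long_acting", config = cfg)
  expect_false(res$disqualifying)

  ## temporary change closed within 31 days
  res <- is_disqualifying_switch(
    change_row(start = 100, end = 131), arm = "long_acting", config = cfg)
  expect_false(res$disqualifying)

  ## permanent switch to standard oral for an adverse event
  res <- is_disqualifying_switch(
    change_row(start = 350, reason = "adverse_event"),
    arm = "long_acting", config = cfg)
  expect_true(res$disqualifying)
  expect_equal(res$change$start_day, 350L)

  ## same change in the oral arm but across class is still a switch
  res <- is_disqualifying_switch(
    change_row(start = 350, within_class = FALSE, reason = "adverse_event"),
    arm = "oral", config = cfg)
  expect_true(res$disqualifying)

  expect_error(
    is_disqualifying_switch(
      rbind(change_row(start = 100), change_row(start = 200)),
      arm = "long_acting", config = cfg),
    class = "virosnap_integrity_error")
})

test_that("classification follows the precedence rules", {
  cfg <- snapshot_config()
  p <- mini_participants(1, arm = "long_acting")

  ## failure switch at week 60 dominates a suppressed week-96 value
  out <- classify_snapshot(
    p, vl_row("T001", 672, copies = 30, lloq = FALSE),
    change_row(start = 420, reason = "virological_failure"), cfg)
  expect_equal(out$category, "nonsuppressed")
  expect_equal(out$reason, "assigned_failure_switch")

  ## withdrawal with no in-window measurement
  pw <- p
  pw$withdrawal_day <- 540L
  out <- classify_snapshot(pw, vl_row("T001", 504),
                           empty_changes(), cfg)
  expect_equal(out$category, "no_data")
  expect_equal(out$reason, "withdrawal")

  ## death takes precedence over withdrawal in the no-data reason
  pd <- pw
  pd$death_day <- 300L
  pd$withdrawal_day <- NA_integer_
  out <- classify_snapshot(pd, empty_vl(), empty_changes(), cfg)
  expect_equal(out$reason, "death")

  ## on-treatment single censored value inside the window
  out <- classify_snapshot(p, vl_row("T001", 672), empty_changes(), cfg)
  expect_equal(out$category, "suppressed")
  expect_equal(out$reason, "observed_vl")

  ## a disqualifying non-failure switch yields no_data
  out <- classify_snapshot(
    p, vl_row("T001", 672),
    change_row(start = 350, reason = "adverse_event"), cfg)
  expect_equal(out$category, "no_data")
  expect_equal(out$reason, "missing_in_window")
})

test_that("window extensions admit a deliberately delayed test", {
  cfg <- snapshot_config(window_extensions = data.frame(
    participant_id = "T001", extended_end_week = 109))
  p <- mini_participants(1, arm = "long_acting")
  out <- classify_snapshot(p, vl_row("T001", 735), empty_changes(), cfg)
  expect_equal(out$category, "suppressed")
  expect_equal(out$vl_day, 735L)
  ## without the extension the same participant has no data
  out2 <- classify_snapshot(p, vl_row("T001", 735), empty_changes(),
                            snapshot_config())
  expect_equal(out2$category, "no_data")
})

test_that("window VL selection prefers closest to week 96, later on ties", {
  cfg <- snapshot_config()
  p <- mini_participants(1, arm = "long_acting")
  vls <- rbind(vl_row("T001", 670, copies = 100, lloq = FALSE),
               vl_row("T001", 674))
  out <- classify_snapshot(p, vls, empty_changes(), cfg)
  expect_equal(out$vl_day, 674L)
  expect_equal(out$category, "suppressed")
})

test_that("snapshot table partitions every arm and is monotone in threshold", {
  empty <- trial_dataset(mini_participants(0))
  tab <- snapshot_table(empty)
  expect_equal(tab$suppressed, c(0L, 0L))
  expect_equal(tab$n, c(0L, 0L))

  ds <- generate_trial(sim_config(seed = 7, n_total = 60))
  t50 <- snapshot_table(ds, snapshot_config(threshold = 50))
  t200 <- snapshot_table(ds, snapshot_config(threshold = 200))
  expect_equal(t50$suppressed + t50$nonsuppressed + t50$no_data, t50$n)
  expect_true(all(t200$suppressed >= t50$suppressed))
  ## idempotence
  expect_identical(snapshot_classify(ds), snapshot_classify(ds))
})
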