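test_that("retest windows follow the arm-specific monitoring rules", {
  la <- monitoring_rule("long_acting")
  oral <- monitoring_rule("oral")

  ## long-acting value 259 at week 72: retest due weeks 76-78
  win <- retest_due(504, 259, FALSE, la)
  expect_equal(win, c(504L + 28L, 504L + 42L))

  ## oral 600 is under the 1000-copy trigger
  expect_null(retest_due(336, 600, FALSE, oral))
  ## boundary inclusive at the trigger
  expect_equal(retest_due(336, 1000, FALSE, oral),
               c(336L + 70L, 336L + 112L))
  expect_equal(retest_due(168, 200, FALSE, la), c(168L + 28L, 168L + 42L))
  ## censored values never trigger
  expect_null(retest_due(336, 0, TRUE, la))
})

test_that("CVF detection finds the first consecutive pair at 200", {
  la <- monitoring_rule("long_acting")
  series <- rbind(vl_row("T001", 168),
                  vl_row("T001", 336, 8608, FALSE),
                  vl_row("T001", 371, 16124, FALSE))
  st <- detect_cvf(series, la)
  expect_true(st$confirmed)
  expect_equal(st$failure_day, 336L)
  expect_equal(st$pair_days, c(336L, 371L))

  ## a single unconfirmed high value with an adjudication record
  single <- rbind(vl_row("T002", 168), vl_row("T002", 336, 44984, FALSE))
  st <- detect_cvf(single, la, adjudicated_day = 336)
  expect_false(st$confirmed)
  expect_true(st$adjudicated_unconfirmed)
  expect_equal(st$failure_day, 336L)

  ## the adjudication must reference a qualifying measurement
  st <- detect_cvf(single, la, adjudicated_day = 168)
  expect_false(st$adjudicated_unconfirmed)

  ## fully suppressed series
  all_low <- rbind(vl_row("T003", 0), vl_row("T003", 168), vl_row("T003", 336))
  st <- detect_cvf(all_low, la)
  expect_false(st$confirmed)
  expect_false(st$adjudicated_unconfirmed)

  ## a pair separated by a suppressed value is not consecutive
  blipped <- rbind(vl_row("T004", 168, 300, FALSE), vl_row("T004", 336),
                   vl_row("T004", 504, 400, FALSE))
  expect_false(detect_cvf(blipped, la)$confirmed)
})

test_that("detection equals a brute-force consecutive-pair scan", {
  la <- monitoring_rule("long_acting")
  set.seed(11)
  for (rep in 1:200) {
    m <- sample(1:6, 1)
    vals <- sample(c(0L, 49L, 120L, 200L, 250L, 900L), m, replace = TRUE)
    days <- sort(sample(seq(0, 700, by = 7), m))
    series <- do.call(rbind, lapply(seq_len(m), function(i) {
      vl_row("X", days[i], vals[i], lloq = vals[i] < 50)
    }))
    st <- detect_cvf(series, la)
    high <- vals >= 200
    brute <- which(high[-m] & high[-1])
    expect_equal(st$confirmed, length(brute) > 0)
    if (length(brute)) expect_equal(st$failure_day, days[brute[1]])
  }
})

test_that("right-truncation never moves an established failure earlier", {
  la <- monitoring_rule("long_acting")
  set.seed(12)
  for (rep in 1:50) {
    m <- sample(3:8, 1)
    vals <- sample(c(0L, 250L, 500L), m, replace = TRUE, prob = c(.5, .3, .2))
    days <- sort(sample(seq(0, 700, by = 7), m))
    series <- do.call(rbind, lapply(seq_len(m), function(i) {
      vl_row("X", days[i], vals[i], lloq = vals[i] < 50)
    }))
    full <- detect_cvf(series, la)
    trunc <- detect_cvf(series[seq_len(m - 1), , drop = FALSE], la)
    if (trunc$confirmed) {
      expect_true(full$confirmed)
      expect_equal(full$failure_day, trunc$failure_day)
    }
  }
})

test_that("fixture CVF counts honour the adjudication switch", {
  ds <- make_fixture()
  with_adj <- cvf_table(ds, count_adjudicated = TRUE)
  expect_equal(with_adj$failures, c(4L, 0L))
  expect_equal(with_adj$n, c(255L, 257L))
  without <- cvf_table(ds, count_adjudicated = FALSE)
  expect_equal(without$failures, c(3L, 0L))

  ## a no-failure simulation yields zero counts
  quiet <- generate_trial(sim_config(seed = 5, n_total = 40,
                                     cvf_hazard = c(long_acting = 0, oral = 0),
                                     withdrawal_prob = 0, death_prob = 0))
  expect_equal(cvf_table(quiet)$failures, c(0L, 0L))
})
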