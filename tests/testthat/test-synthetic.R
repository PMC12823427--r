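test_that("generation is reproducible under a seed and varies across seeds", {
  cfg <- sim_config(seed = 3, n_total = 50)
  a <- generate_trial(cfg)
  b <- generate_trial(cfg)
  for (name in names(a)) expect_identical(a[[name]], b[[name]])

  c_ <- generate_trial(sim_config(seed = 4, n_total = 50))
  expect_false(identical(a$viral_loads, c_$viral_loads))

  ## the generator does not disturb the caller's RNG stream
  set.seed(99)
  before <- runif(1)
  set.seed(99)
  invisible(generate_trial(cfg))
  expect_identical(runif(1), before)
})

test_that("degenerate settings give complete suppression", {
  cfg <- sim_config(seed = 8, n_total = 60,
                    p_suppress = c(long_acting = 1, oral = 1),
                    cvf_hazard = c(long_acting = 0, oral = 0),
                    withdrawal_prob = 0, death_prob = 0)
  tab <- snapshot_table(generate_trial(cfg))
  expect_equal(tab$suppressed, tab$n)
  expect_equal(tab$nonsuppressed, c(0L, 0L))
  expect_equal(tab$no_data, c(0L, 0L))
})

test_that("permuted blocks balance arms within strata", {
  ds <- generate_trial(sim_config(seed = 21, n_total = 200, block_size = 4))
  p <- ds$participants
  for (s in unique(p$stratum)) {
    sub <- p[p$stratum == s, ]
    expect_lte(abs(sum(sub$arm == "long_acting") - sum(sub$arm == "oral")),
               2L)
  }
})

test_that("invalid configurations are rejected", {
  expect_error(sim_config(), class = "virosnap_config_error")
  expect_error(sim_config(seed = 1, withdrawal_prob = 1.2),
               class = "virosnap_config_error")
  expect_error(sim_config(seed = 1, block_size = 3),
               class = "virosnap_config_error")
  expect_error(sim_config(seed = 1, n_total = 1),
               class = "virosnap_config_error")
  expect_error(sim_config(seed = 1, delay_probs = c(0.5, 0.5, 0.1, 0.1)),
               class = "virosnap_config_error")
})

test_that("the default fixture reproduces the reference outcome counts", {
  ds <- make_fixture()
  snap <- snapshot_table(ds)
  expect_equal(snap$suppressed, c(247L, 250L))
  expect_equal(snap$nonsuppressed, c(4L, 2L))
  expect_equal(snap$no_data, c(4L, 5L))
  expect_equal(cvf_table(ds)$failures, c(4L, 0L))
  pops <- population_summary(ds)
  expect_equal(pops$per_protocol, c(224L, 215L))
  ## deterministic construction
  expect_identical(make_fixture()$viral_loads, ds$viral_loads)
})

test_that("fixture specifications generalize beyond the default counts", {
  ## minimal single-arm partition 1/1/1
  spec <- fixture_spec(
    long_acting = fixture_arm(n = 3, suppressed = 1,
                              observed_nonsuppressed = 1, withdrawals = 1),
    oral = fixture_arm(n = 0, suppressed = 0))
  tab <- snapshot_table(make_fixture(spec))
  la <- tab[tab$arm == "long_acting", ]
  expect_equal(c(la$suppressed, la$nonsuppressed, la$no_data), c(1L, 1L, 1L))

  ## inconsistent counts are rejected
  expect_error(fixture_arm(n = 3, suppressed = 3, withdrawals = 1),
               class = "virosnap_config_error")
  expect_error(fixture_arm(n = 10, suppressed = 9, deaths = 1,
                           adjudicated_failures = 2),
               class = "virosnap_config_error")
})

test_that("a threshold-200 fixture variant reproduces the secondary row", {
  spec <- fixture_spec(
    long_acting = fixture_arm(
      n = 255, suppressed = 249, assigned_failure = 2, withdrawals = 3,
      deaths = 1, adjudicated_failures = 0),
    oral = fixture_arm(
      n = 257, suppressed = 251, observed_nonsuppressed = 1,
      withdrawals = 4, deaths = 1, nonsupp_copies = 600L))
  tab <- snapshot_table(make_fixture(spec), snapshot_config(threshold = 200))
  expect_equal(tab$suppressed, c(249L, 251L))
  expect_equal(tab$nonsuppressed, c(2L, 1L))
  expect_equal(tab$no_data, c(4L, 5L))
})
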