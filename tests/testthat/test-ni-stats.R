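test_that("MN score CI matches the independent grid-search oracle", {
  ## expected values frozen from mn_grid_oracle() (numerical restricted MLE,
  ## 1e-6 grid): (2,10,1,10) -> (-25.9459, 44.5370); (4,255,0,257) ->
  ## (0.0814, 3.9665)
  ci <- mn_score_ci(2, 10, 1, 10)
  expect_equal(ci$estimate, 10)
  expect_equal(ci$lower, -25.9459, tolerance = 1e-3)
  expect_equal(ci$upper, 44.5370, tolerance = 1e-3)

  ci <- mn_score_ci(4, 255, 0, 257)
  expect_equal(ci$estimate, 100 * (4 / 255), tolerance = 1e-10)
  expect_equal(ci$lower, 0.0814, tolerance = 1e-3)
  expect_equal(ci$upper, 3.9665, tolerance = 1e-3)
})

test_that("MN interval is finite and positive at a zero count in one arm", {
  ci <- mn_score_ci(4, 255, 0, 257)
  expect_true(is.finite(ci$lower) && ci$lower > 0)
  ## the Wald interval lacks this property only through its zero-variance
  ## arm; the score interval must bracket the estimate as well
  expect_true(ci$lower <= ci$estimate && ci$estimate <= ci$upper)
})

test_that("MN bounds bracket the estimate and width shrinks with n", {
  cases <- list(c(2, 10, 1, 10), c(20, 100, 10, 100), c(0, 50, 3, 60),
                c(47, 50, 44, 50), c(5, 12, 5, 13))
  for (cs in cases) {
    ci <- mn_score_ci(cs[1], cs[2], cs[3], cs[4])
    expect_lte(ci$lower, ci$estimate)
    expect_gte(ci$upper, ci$estimate)
  }
  small <- mn_score_ci(20, 100, 10, 100)
  large <- mn_score_ci(200, 1000, 100, 1000)
  expect_lt(large$upper - large$lower, small$upper - small$lower)
})

test_that("all-zero tables give a symmetric interval around zero", {
  ci <- mn_score_ci(0, 100, 0, 100)
  expect_equal(ci$estimate, 0)
  expect_equal(ci$lower, -ci$upper, tolerance = 1e-6)
  ## idempotence of the solver
  ci2 <- mn_score_ci(0, 100, 0, 100)
  expect_identical(ci$lower, ci2$lower)
})

test_that("score roots satisfy the score equation to high accuracy", {
  ci <- mn_score_ci(4, 255, 0, 257)
  strata <- data.frame(x1 = 4, n1 = 255, x2 = 0, n2 = 257)
  zq <- qnorm(0.975)
  expect_lt(abs(virosnap:::cmh_mn_z(strata, ci$lower / 100) - zq), 1e-8)
  expect_lt(abs(virosnap:::cmh_mn_z(strata, ci$upper / 100) + zq), 1e-8)
})

test_that("CMH-MN with one stratum equals the unstratified interval exactly", {
  single <- cmh_mn_ci(data.frame(x1 = 4, n1 = 255, x2 = 0, n2 = 257))
  plain <- mn_score_ci(4, 255, 0, 257)
  expect_identical(single$estimate, plain$estimate)
  expect_identical(single$lower, plain$lower)
  expect_identical(single$upper, plain$upper)
})

test_that("CMH-MN weighting behaves as expected", {
  ## two identical strata: estimate equals the common stratum difference
  two <- cmh_mn_ci(data.frame(x1 = c(2, 2), n1 = c(128, 128),
                              x2 = c(1, 1), n2 = c(129, 129)))
  expect_equal(two$estimate, 100 * (2 / 128 - 1 / 129), tolerance = 1e-10)

  ## a dominant and a tiny stratum: estimate near the crude difference
  strat <- cmh_mn_ci(data.frame(x1 = c(240, 7), n1 = c(247, 8),
                                x2 = c(243, 7), n2 = c(250, 7)))
  crude <- 100 * (247 / 255 - 250 / 257)
  expect_lt(abs(strat$estimate - crude), 0.2)

  ## a stratum with an empty arm is dropped with a warning
  expect_warning(
    dropped <- cmh_mn_ci(data.frame(x1 = c(4, 0), n1 = c(255, 0),
                                    x2 = c(0, 2), n2 = c(257, 20))),
    "empty arm")
  expect_identical(dropped$lower, mn_score_ci(4, 255, 0, 257)$lower)
})

test_that("Wald intervals reproduce the adverse-event table rows", {
  ci <- wald_ci(41, 255, 22, 257)
  expect_equal(round_half_away(ci$estimate, 1), 7.5)
  expect_equal(round_half_away(ci$lower, 1), 1.9)
  expect_equal(round_half_away(ci$upper, 1), 13.2)

  ci <- wald_ci(12, 255, 9, 257)
  expect_equal(round_half_away(ci$estimate, 1), 1.2)
  expect_equal(round_half_away(ci$lower, 1), -2.2)
  expect_equal(round_half_away(ci$upper, 1), 4.6)

  sym <- wald_ci(30, 100, 30, 100)
  expect_equal(sym$estimate, 0)
  expect_equal(sym$lower, -sym$upper)

  degen <- wald_ci(0, 50, 0, 60)
  expect_equal(degen$lower, degen$estimate)
  expect_equal(degen$upper, degen$estimate)
})

test_that("Wald and MN intervals agree asymptotically", {
  w <- wald_ci(30000, 1e5, 30500, 1e5)
  m <- mn_score_ci(30000, 1e5, 30500, 1e5)
  expect_lt(abs(w$lower - m$lower), 0.1)
  expect_lt(abs(w$upper - m$upper), 0.1)
})

test_that("homogeneity test detects discordance and not identity", {
  same <- homogeneity_test(data.frame(x1 = c(20, 40), n1 = c(100, 200),
                                      x2 = c(10, 20), n2 = c(100, 200)))
  expect_equal(unname(same$statistic), 0)
  expect_equal(same$p.value, 1)

  opp <- homogeneity_test(data.frame(x1 = c(90, 10), n1 = c(100, 100),
                                     x2 = c(10, 90), n2 = c(100, 100)))
  expect_lt(opp$p.value, 0.05)

  expect_error(homogeneity_test(data.frame(x1 = 1, n1 = 10, x2 = 1,
                                           n2 = 10)),
               class = "virosnap_domain_error")
})

test_that("noninferiority decisions use the right bound, strictly", {
  rd <- function(lower, upper) {
    virosnap:::new_riskdiff((lower + upper) / 2, lower, upper, 0.05,
                            "mn_score", NULL)
  }
  expect_true(noninferiority_decision(rd(-3.1, 2.0), 10, "lower")$met)
  expect_false(noninferiority_decision(rd(0.4, 4.2), 4, "upper")$met)
  ## a bound exactly on the margin does not meet the criterion
  expect_false(noninferiority_decision(rd(-10.0, 2.0), 10, "lower")$met)
  expect_false(noninferiority_decision(rd(0.0, 4.0), 4, "upper")$met)
})

test_that("noninferiority sample size matches the closed form", {
  expect_identical(ni_sample_size(0.94, margin = 0.10), 119L)
  ## closed-form arithmetic oracle at 50% power (z_power = 0)
  oracle <- as.integer(ceiling(qnorm(0.975)^2 * 2 * 0.94 * 0.06 / 0.10^2))
  expect_identical(ni_sample_size(0.94, margin = 0.10, power = 0.5), oracle)
  ## quadratic scaling in the margin (before rounding)
  raw <- (qnorm(0.975) + qnorm(0.90))^2 * 2 * 0.94 * 0.06
  expect_identical(ni_sample_size(0.94, margin = 0.05),
                   as.integer(ceiling(raw / 0.05^2)))
  expect_equal(ni_sample_size(0.94, margin = 0.05),
               as.integer(ceiling(4 * raw / 0.10^2)))
  expect_error(ni_sample_size(0.94, 0.80, margin = 0.10),
               class = "virosnap_domain_error")
})
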