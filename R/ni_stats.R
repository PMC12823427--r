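## Risk-difference estimation and noninferiority machinery.
##
## The score-based interval follows Miettinen & Nurminen: the confidence
## bounds for the difference delta = p1 - p2 are the values where
##
##   z(delta) = (p1hat - p2hat - delta) / se(delta)
##
## equals the +/- normal quantile, with se(delta)^2 the binomial variance
## evaluated at the maximum-likelihood estimates of (p1, p2) restricted to
## p1 - p2 = delta, inflated by N/(N-1). The restricted MLEs have a closed
## cubic solution; z(delta) is strictly decreasing in delta, so the bounds
## are found by bisection.

## restricted MLEs of (p1, p2) under p1 - p2 = delta (closed-form cubic);
## vectorized over delta
mn_rmle <- function(p1hat, p2hat, n1, n2, delta) {
  theta <- n2 / n1
  a <- 1 + theta
  b <- -(1 + theta + p1hat + theta * p2hat + delta * (theta + 2))
  cc <- delta^2 + delta * (2 * p1hat + theta + 1) + p1hat + theta * p2hat
  dd <- -p1hat * delta * (1 + delta)
  v <- b^3 / (3 * a)^3 - b * cc / (6 * a^2) + dd / (2 * a)
  u <- sign(v + (v == 0)) * sqrt(pmax(0, b^2 / (3 * a)^2 - cc / (3 * a)))
  ratio <- ifelse(u == 0, 0, v / u^3)
  w <- (pi + acos(pmin(1, pmax(-1, ratio)))) / 3
  p1t <- 2 * u * cos(w) - b / (3 * a)
  p1t <- pmin(1, pmax(0, p1t))
  p2t <- pmin(1, pmax(0, p1t - delta))
  list(p1 = p1t, p2 = p2t)
}

## stratified score statistic; `strata` is a data.frame with x1,n1,x2,n2.
## With one stratum the weights cancel and this is exactly the
## Miettinen-Nurminen statistic.
cmh_mn_z <- function(strata, delta) {
  w <- strata$n1 * strata$n2 / (strata$n1 + strata$n2)
  d_k <- strata$x1 / strata$n1 - strata$x2 / strata$n2
  t_k <- mn_rmle(strata$x1 / strata$n1, strata$x2 / strata$n2,
                 strata$n1, strata$n2, delta)
  nk <- strata$n1 + strata$n2
  v_k <- (t_k$p1 * (1 - t_k$p1) / strata$n1 +
            t_k$p2 * (1 - t_k$p2) / strata$n2) * nk / (nk - 1)
  num <- sum(w * (d_k - delta)) / sum(w)
  den <- sqrt(sum(w^2 * v_k)) / sum(w)
  if (den == 0) {
    if (num == 0) return(0)
    return(sign(num) * Inf)
  }
  num / den
}

## bisection for the delta where cmh_mn_z equals `target`; z is decreasing in
## delta so the sign of f = z - target brackets cleanly
mn_solve <- function(strata, target, lower, upper, tol = 1e-11) {
  f <- function(d) cmh_mn_z(strata, d) - target
  lo <- lower
  hi <- upper
  flo <- f(lo)
  fhi <- f(hi)
  if (flo < 0 || fhi > 0) {
    vs_stop("virosnap_domain_error", "score equation not bracketed")
  }
  while (hi - lo > tol) {
    mid <- (lo + hi) / 2
    if (f(mid) >= 0) lo <- mid else hi <- mid
  }
  (lo + hi) / 2
}

new_riskdiff <- function(estimate, lower, upper, alpha, method, counts) {
  structure(
    list(estimate = estimate, lower = lower, upper = upper,
         alpha = alpha, method = method, counts = counts),
    class = "riskdiff"
  )
}

check_2x2 <- function(x1, n1, x2, n2) {
  if (!is_count(n1) || !is_count(n2) || n1 < 1 || n2 < 1) {
    vs_stop("virosnap_domain_error", "group sizes must be positive integers")
  }
  if (!is_count(x1) || !is_count(x2) || x1 > n1 || x2 > n2) {
    vs_stop("virosnap_domain_error", "event counts must satisfy 0 <= x <= n")
  }
}

#' Miettinen-Nurminen score confidence interval for a risk difference
#'
#' Computes the two-sided score interval for `p1 - p2` from independent
#' binomial counts, using the restricted-MLE variance with the `N/(N-1)`
#' inflation factor. The interval is well defined at zero or saturated event
#' counts (where the Wald interval degenerates): for example `x2 = 0` still
#' yields a finite positive lower bound when `x1 > 0`.
#'
#' @param x1,n1 events and group size, first group (e.g. long-acting arm).
#' @param x2,n2 events and group size, second group (e.g. oral arm).
#' @param alpha two-sided significance level (default 0.05 for a 95% CI).
#' @return a `riskdiff` object; `estimate`, `lower`, `upper` are in
#'   percentage points.
#' @export
#' @examples
#' mn_score_ci(4, 255, 0, 257)
mn_score_ci <- function(x1, n1, x2, n2, alpha = 0.05) {
  check_2x2(x1, n1, x2, n2)
  strata <- data.frame(x1 = x1, n1 = n1, x2 = x2, n2 = n2)
  ci <- cmh_mn_core(strata, alpha)
  new_riskdiff(ci$estimate, ci$lower, ci$upper, alpha, "mn_score",
               strata)
}

cmh_mn_core <- function(strata, alpha) {
  z <- stats::qnorm(1 - alpha / 2)
  w <- strata$n1 * strata$n2 / (strata$n1 + strata$n2)
  d_k <- strata$x1 / strata$n1 - strata$x2 / strata$n2
  dhat <- sum(w * d_k) / sum(w)
  eps <- 1e-12
  lower <- mn_solve(strata, z, -1 + eps, dhat)
  upper <- mn_solve(strata, -z, dhat, 1 - eps)
  list(estimate = 100 * dhat, lower = 100 * lower, upper = 100 * upper)
}

#' Stratified (CMH-weighted) Miettinen-Nurminen confidence interval
#'
#' Pools stratum-specific risk differences with Cochran-Mantel-Haenszel
#' weights `n1k * n2k / (n1k + n2k)` and inverts the weighted score
#' statistic, in which each stratum contributes its restricted-MLE variance
#' evaluated at the common difference. With a single stratum the result
#' equals [mn_score_ci()] exactly. Strata with an empty arm carry no
#' information about the difference and are dropped with a warning.
#'
#' @param strata data frame with columns `x1`, `n1`, `x2`, `n2` (one row per
#'   stratum); an optional `stratum` column labels rows in messages.
#' @param alpha two-sided significance level.
#' @return a `riskdiff` object (percentage points), method `"cmh_mn_score"`.
#' @export
#' @examples
#' cmh_mn_ci(data.frame(x1 = c(240, 7), n1 = c(247, 8),
#'                      x2 = c(243, 7), n2 = c(250, 7)))
cmh_mn_ci <- function(strata, alpha = 0.05) {
  stopifnot(is.data.frame(strata),
            all(c("x1", "n1", "x2", "n2") %in% names(strata)))
  empty <- strata$n1 == 0 | strata$n2 == 0
  if (any(empty)) {
    warning(sprintf("dropping %d stratum/strata with an empty arm",
                    sum(empty)))
    strata <- strata[!empty, , drop = FALSE]
  }
  if (!nrow(strata)) {
    vs_stop("virosnap_domain_error", "no stratum with both arms represented")
  }
  for (i in seq_len(nrow(strata))) {
    check_2x2(strata$x1[i], strata$n1[i], strata$x2[i], strata$n2[i])
  }
  ci <- cmh_mn_core(strata, alpha)
  new_riskdiff(ci$estimate, ci$lower, ci$upper, alpha, "cmh_mn_score",
               strata)
}

#' Wald (normal-approximation) confidence interval for a risk difference
#'
#' `estimate +/- z * sqrt(p1(1-p1)/n1 + p2(1-p2)/n2)`, in percentage points.
#' With zero variance in both groups the interval degenerates to the
#' estimate.
#'
#' @inheritParams mn_score_ci
#' @return a `riskdiff` object, method `"wald"`.
#' @export
#' @examples
#' wald_ci(41, 255, 22, 257)
wald_ci <- function(x1, n1, x2, n2, alpha = 0.05) {
  check_2x2(x1, n1, x2, n2)
  p1 <- x1 / n1
  p2 <- x2 / n2
  z <- stats::qnorm(1 - alpha / 2)
  se <- sqrt(p1 * (1 - p1) / n1 + p2 * (1 - p2) / n2)
  new_riskdiff(100 * (p1 - p2), 100 * (p1 - p2 - z * se),
               100 * (p1 - p2 + z * se), alpha, "wald",
               data.frame(x1 = x1, n1 = n1, x2 = x2, n2 = n2))
}

#' Homogeneity test for risk differences across subgroup levels
#'
#' Weighted chi-square test of whether level-specific risk differences share
#' a common value: the differences are centred on their Cochran-Mantel-
#' Haenszel-weighted mean and summed as `(d_k - dbar)^2 / v_k` with `v_k`
#' the estimated binomial variance of `d_k`; the statistic is referred to a
#' chi-square distribution on `levels - 1` degrees of freedom. Levels with
#' zero weight (an empty arm) are dropped.
#'
#' @param levels data frame with one row per subgroup level, columns `x1`,
#'   `n1`, `x2`, `n2`.
#' @return an object of class `htest`.
#' @export
homogeneity_test <- function(levels) {
  dname <- deparse(substitute(levels))
  stopifnot(is.data.frame(levels),
            all(c("x1", "n1", "x2", "n2") %in% names(levels)))
  keep <- levels$n1 > 0 & levels$n2 > 0
  levels <- levels[keep, , drop = FALSE]
  if (nrow(levels) < 2) {
    vs_stop("virosnap_domain_error",
            "homogeneity test needs at least two informative levels")
  }
  p1 <- levels$x1 / levels$n1
  p2 <- levels$x2 / levels$n2
  d_k <- p1 - p2
  w <- levels$n1 * levels$n2 / (levels$n1 + levels$n2)
  v_k <- p1 * (1 - p1) / levels$n1 + p2 * (1 - p2) / levels$n2
  dbar <- sum(w * d_k) / sum(w)
  ok <- v_k > 0
  stat <- sum((d_k[ok] - dbar)^2 / v_k[ok])
  df <- nrow(levels) - 1L
  p <- stats::pchisq(stat, df, lower.tail = FALSE)
  structure(
    list(statistic = c(`X-squared` = stat),
         parameter = c(df = df),
         p.value = p,
         method = "CMH-weighted homogeneity test of risk differences",
         data.name = dname),
    class = "htest"
  )
}

#' Noninferiority decision from a confidence interval
#'
#' Applies the prespecified margin to one bound of a two-sided interval:
#' with `bound = "lower"` (e.g. a suppression outcome) noninferiority is met
#' when the lower limit lies strictly above `-margin`; with
#' `bound = "upper"` (e.g. a failure outcome) when the upper limit lies
#' strictly below `+margin`.
#'
#' @param ci a `riskdiff` object (bounds in percentage points).
#' @param margin positive noninferiority margin in percentage points.
#' @param bound which CI bound the criterion uses.
#' @return a list with `margin`, `bound_used`, `met`.
#' @export
noninferiority_decision <- function(ci, margin, bound = c("lower", "upper")) {
  bound <- match.arg(bound)
  stopifnot(inherits(ci, "riskdiff"), is.numeric(margin), margin > 0)
  met <- if (bound == "lower") ci$lower > -margin else ci$upper < margin
  list(margin = margin, bound_used = bound, met = met)
}

#' Sample size for a noninferiority comparison of two proportions
#'
#' Per-group sample size for showing noninferiority of a difference in
#' proportions at margin `margin`, two-sided level `alpha` and the given
#' power, by the standard normal-approximation formula
#' `(z[1-alpha/2] + z[power])^2 * (p1 q1 + p2 q2) / (margin - |p1 - p2|)^2`,
#' rounded up.
#'
#' @param p1,p2 assumed true proportions under the alternative.
#' @param margin noninferiority margin (absolute difference scale).
#' @param alpha two-sided significance level.
#' @param power target power.
#' @return integer sample size per group.
#' @export
#' @examples
#' ni_sample_size(0.94, 0.94, margin = 0.10)  # 119 per group
ni_sample_size <- function(p1, p2 = p1, margin, alpha = 0.05, power = 0.90) {
  stopifnot(p1 > 0, p1 < 1, p2 > 0, p2 < 1, margin > 0, margin < 1)
  if (margin <= abs(p1 - p2)) {
    vs_stop("virosnap_domain_error",
            "margin must exceed |p1 - p2|; no power to show noninferiority")
  }
  z_a <- stats::qnorm(1 - alpha / 2)
  z_b <- stats::qnorm(power)
  n <- (z_a + z_b)^2 * (p1 * (1 - p1) + p2 * (1 - p2)) /
    (margin - abs(p1 - p2))^2
  as.integer(ceiling(n))
}

#' @export
print.riskdiff <- function(x, ...) {
  cat(sprintf("Risk difference (%s): %.1f percentage points\n",
              x$method, round_half_away(x$estimate, 1)))
  cat(sprintf("%.0f%% CI: %.1f to %.1f\n", 100 * (1 - x$alpha),
              round_half_away(x$lower, 1), round_half_away(x$upper, 1)))
  invisible(x)
}

#' @export
format.riskdiff <- function(x, ...) {
  sprintf("%.1f (%.1f to %.1f)", round_half_away(x$estimate, 1),
          round_half_away(x$lower, 1), round_half_away(x$upper, 1))
}
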