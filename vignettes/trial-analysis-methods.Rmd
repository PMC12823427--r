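---
title: "Methods: snapshot classification, failure detection and noninferiority statistics"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: snapshot classification, failure detection and noninferiority statistics}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(virosnap)
```

## The analysis problem

`virosnap` implements the virologic-outcome analysis of a two-arm randomized
switch trial in which virally suppressed adults either switch to long-acting
injectable cabotegravir and rilpivirine or continue daily oral therapy, under
a public-health monitoring schedule: viral load is measured only every 24
weeks, and retesting rules differ by arm. The package covers five linked
stages — outcome classification, analysis-population derivation,
confirmed-failure detection, APOBEC-aware resistance filtering, and
noninferiority statistics — plus a simulator and a deterministic fixture so
that every stage can be exercised without participant-level trial data.

Time is handled as integer study days: randomization is day 0 and nominal
week $w$ is day $7w$. This turns all window logic into integer comparisons.
Censored viral loads (reported as "<50 copies/ml") are stored as a boolean
`below_lloq` with the numeric field zeroed; every threshold comparison
consults the boolean first, so no sentinel value can leak into arithmetic.

## Modified FDA snapshot classification

The week-96 outcome classifies each participant as *suppressed*,
*nonsuppressed* or *no virologic data* from the viral load measured in a
prespecified window of weeks 84–102, read inclusively as days 588–714. Three
kinds of regimen change are exempted from counting as treatment switches:
temporary changes closed within 31 days; oral bridging of the long-acting
drugs followed by a return to injections; and within-class changes in the
oral arm. A disqualifying switch made for virological failure before the end
of the window assigns the participant to nonsuppressed regardless of any
in-window measurement — this is what makes resuppressed-after-switch
participants count as failures in the primary table.

Where the underlying rules are silent, the package fixes these behaviours:

* **Several in-window measurements.** The measurement closest in study days
  to day 672 is used, ties resolved toward the later measurement. This
  matches usual snapshot practice of anchoring on the nominal visit.
* **Disqualifying switch for a non-failure reason.** The participant is
  classified `no_data` with the disposition-derived reason, even if an
  in-window measurement exists; a *non*-disqualifying change never blocks
  classification from the measurement.
* **`no_data` reason precedence.** Death, then withdrawal, then
  missing-in-window, so each participant carries exactly one reason.
* **Window extensions.** A per-participant extension list admits tests
  deliberately delayed past week 102 (e.g. to coincide with a rescheduled
  injection visit) without changing the window for anyone else.

Two invariants are enforced by construction and tested: the three categories
always partition each arm, and raising the threshold (50 to 200 copies/ml)
never decreases the suppressed count.

## Analysis populations

The intention-to-treat exposed (ITT-E) population is everyone who received
at least one dose of the assigned intervention. The per-protocol population
removes, in a fixed precedence order, participants who (1) withdrew or died
before week 96, (2) had an injection more than 14 days after its target date
without oral bridging, or (3) missed more than 7 days of oral treatment at
one or more dispensing visits. The precedence gives each excluded
participant exactly one reason, so per-arm exclusion counts reconstruct the
population size exactly (on the shipped fixture: 255 − 4 − 22 − 5 = 224 and
257 − 5 − 37 = 215). The complete-case population is ITT-E restricted to
participants with an in-window measurement.

Injection delay is measured against the randomization-anchored target
schedule (weeks 4, 8, 16, …, 96), not against the previous actual injection:
targets are what the phrase "target date" denotes, and schedule anchoring is
reproducible from the randomization day alone. Days covered by an oral
bridging interval are subtracted from the delay. When bridging covers the
delay only partially, the subtracted days are those of the bridge interval
overlapping `[target, actual]`; the overlap rule is a package decision since
only the exclusion principle itself is specified, and it is symmetric in
where the bridge sits inside the delay.

A delay of exactly 14 days is retained ("more than 14 days" is strict); the
boundary is tested.

## Confirmed virological failure

Monitoring is arm specific: a long-acting-arm value ≥200 copies/ml prompts a
retest after 4–6 weeks; the oral arm uses a ≥1000 trigger with a 10–16 week
retest, allowing adherence counselling first. Confirmed virological failure
(CVF) is two *consecutive* measurements ≥200 copies/ml. "Consecutive" means
adjacent in the participant's day-sorted series regardless of spacing: the
retest windows govern when measurements are generated, not how the
definition reads. The failure day is the day of the first of the pair, which
makes the detection stable under right-truncation of the series (adding
later data can never move an established failure earlier — a tested
property).

A single ≥200 measurement that could never be confirmed (e.g. the
participant died before the retest) can be *adjudicated* as a failure. The
adjudication is always an explicit input record naming the measurement day —
it is never inferred from the data, because the one situation it models is a
clinical judgment. Whether adjudicated cases count as failures is a pipeline
switch (`count_adjudicated_cvf`, default on).

An oral-arm participant can in principle hold two consecutive values in
[200, 1000) without ever triggering a retest; the definitions pull in
opposite directions there. The detector counts such a pair (the definition
is measurement-based), and the generator does not produce the ambiguous case
under default settings.

## APOBEC-context resistance filtering

Host APOBEC enzymes hypermutate archived proviral DNA, which can fabricate
apparent drug-resistance mutations on virus that is defective and cannot
replicate. The filter therefore disregards a resistance call exactly when
both conditions hold: the call's gene, position and an observed mutant amino
acid are in the 14-item APOBEC-context set (RT 67N, 138K, 184I, 190E, 190S,
230I; IN 118R, 138K, 140R, 140S, 163K, 163R, 232N, 263K), and the carrying
sequence shows independent evidence of APOBEC activity — at least one
signature hypermutation or at least one stop codon. All other listed
mutations are retained irrespective of evidence. Consequences that are
tested as properties: filtering never increases prevalence, is idempotent,
and equals a brute-force set-comprehension oracle on randomized inputs.

Mixtures such as `K103N/S` are parsed into observed sets with the reference
letter dropped (`M230M/L` observes only `L`), and a call matches a list
entry if *any* observed mutant matches — the conservative reading of
mutation-list matching. Residue strings carry one character per reference
position with bracket groups for ambiguous positions (`"PIS[NS]ETP"`), so
signature matching needs no external alignment machinery.

The signature lists themselves (154 reverse-transcriptase and 95 integrase
signature mutations in the curated public database) are reference data, not
algorithm: they ship as editable CSV files, and the files installed with the
package are small synthetic defaults, clearly named as such. Every test uses
synthetic lists, so correctness of the filter is independent of any
transcription of the database. Susceptibility levels (low/intermediate/high)
are out of scope except as a user-supplied lookup: the package deliberately
implements no scoring engine.

## Noninferiority statistics

The central estimator is the Miettinen–Nurminen (MN) score interval for a
difference of proportions $\delta = p_1 - p_2$. The bounds are the values of
$\delta$ where

$$ z(\delta) \;=\; \frac{\hat p_1 - \hat p_2 - \delta}
   {\sqrt{\left[\tilde p_1(1-\tilde p_1)/n_1 + \tilde p_2(1-\tilde p_2)/n_2\right]\; N/(N-1)}} $$

equals $\pm z_{1-\alpha/2}$, with $(\tilde p_1, \tilde p_2)$ the maximum
likelihood estimates restricted to $\tilde p_1 - \tilde p_2 = \delta$. The
$N/(N-1)$ factor is what distinguishes the MN form from Farrington–Manning.
Numerical choices: the restricted MLEs use the closed-form cubic solution
(trigonometric form, with the degenerate-discriminant branches clamped);
$z(\delta)$ is strictly decreasing in $\delta$, so each bound is found by
bisection on $[-1, 1]$ to a $\delta$-tolerance of $10^{-11}$, which places
the root within $10^{-8}$ of the quantile on the $z$ scale. The interval is
well defined at zero counts: for 4/255 versus 0/257 events the package
computes a difference of 1.6 percentage points with 95% bounds 0.1 and 4.0
(one-decimal rounding, half away from zero — the convention used for all
reported percentages).

The stratified version pools stratum differences with
Cochran–Mantel–Haenszel weights $w_k = n_{1k}n_{2k}/(n_{1k}+n_{2k})$ and
inverts

$$ z(\delta) = \frac{\sum_k w_k(\hat d_k - \delta)}
   {\sqrt{\sum_k w_k^2 \tilde v_k(\delta)}}, $$

each stratum contributing its restricted-MLE variance at the common
$\delta$. With one stratum the weights cancel and the result is *identical*
(same code path, tested to exact equality) to the unstratified interval.
Strata with an empty arm carry no information about the difference and are
dropped with a warning.

Noninferiority decisions use strict inequalities on the prespecified bound:
the suppression outcome requires the lower 95% limit above −10 percentage
points; confirmed virological failure requires the upper limit below +4. The
supporting sample-size calculation uses the standard normal-approximation
formula; with 94% suppression assumed in both groups, a 10% margin, 5%
two-sided alpha and 90% power it returns 119 per group.

The homogeneity test for subgroup analyses centres level-specific risk
differences on their CMH-weighted mean and sums
$(d_k - \bar d_w)^2/\hat v_k$ with unpooled binomial variances, referred to
$\chi^2_{K-1}$. The exact form of the "CMH homogeneity test" is not uniquely
determined by its name; this weighted least-squares form was chosen because
CMH weights are proportional to inverse variances under a common event rate,
making the statistic asymptotically calibrated — its simulated type-I error
at two levels of 300 participants per arm is close to the nominal 5% (the
acceptance suite checks 1000 replicates against a 3-standard-error band).

The adverse-event table uses ordinary Wald (normal-approximation) intervals,
matching how safety rows are conventionally reported; with zero variance in
both arms the interval degenerates to the estimate.

## The synthetic generator and the fixture

Two data sources ship with the package, with different jobs:

* `generate_trial()` draws a seeded random dataset with the statistical
  structure the analysis assumes. Defaults are calibrated once to the
  marginal frequencies of the reference 512-participant trial: 97% week-96
  suppression, a per-visit rebound hazard of 0.004 in the long-acting arm
  (≈1.6% cumulative over four monitored visits) and zero in the oral arm,
  delay-category probabilities chosen so that about 10% of long-acting
  participants ever exceed a 14-day delay, an 83% no-missed-dose visit rate
  with 1.9% of visits missing more than 7 days, ≈1.8% combined
  withdrawal/death, 8% NNRTI stratum share, and a 12% baseline
  rilpivirine-mutation rate of which 40% sit in APOBEC context on
  hypermutated sequences (so filtering roughly halves prevalence). Where
  only a summary percentage is reported the per-event probabilities are not
  unique; the chosen decomposition is documented here and not revisited.
  Rebound trajectories stay ≥200 copies/ml until a simulated switch and
  resuppress afterwards, so consecutive-pair detection and assigned-failure
  classification are both exercisable. Retest visits are produced by
  applying `retest_due()` to the simulated series, keeping generator and
  detector consistent by construction.
* `make_fixture()` builds a fully deterministic dataset (no random draws)
  whose pipeline outputs reproduce a specified set of marginal counts
  exactly; the default specification carries the reference trial's counts
  (snapshot 247/4/4 versus 250/2/5, failures 4 versus 0 with one
  adjudicated, per-protocol 224/215, complete case 251/252, the
  adverse-event table, and rilpivirine resistance 14/208 filtered versus
  25/208 unfiltered).

What the generator does *not* emulate: pharmacokinetics, correlation between
adverse events and virologic outcomes beyond the switch-on-failure link,
calendar time, assay-level measurement error, or between-site heterogeneity.
Passing tests on generated data therefore demonstrate correctness of the
classification and statistical machinery under the assumed structure, not
robustness to real-data messiness.

## Problem sizes and determinism

The test suite runs the fixture (512 participants) throughout, a 10,000
participant generation for the parameter-recovery check, 1000-replicate
simulations for the homogeneity calibration and the filter oracle, and a
1e-6 grid scan for the score-equation oracle; the whole suite completes in
well under a minute on one core. Every random quantity flows through an
explicit seed (`sim_config()` refuses to run without one), the generator
restores the caller's RNG state, and the fixture and pipeline are fully
deterministic, so identical inputs and configuration yield byte-identical
reports.

## Known limitations

* The full FDA snapshot reason taxonomy (sub-codes for discontinuation
  categories) is collapsed to the categories the analysis reports.
* Susceptibility scoring, subtype assignment, questionnaire scoring,
  body-composition analyses and sensitivity models (modified Poisson with
  sandwich variance) are out of scope.
* The shipped drug-resistance and signature lists are synthetic stand-ins
  sized for testing; real analyses must supply transcriptions of the
  curated databases.
* The stratified interval assumes a common true difference across strata;
  with strong qualitative interaction the pooled estimate is not
  interpretable (use the homogeneity test first).
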