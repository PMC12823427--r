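# virosnap

Virologic outcome classification and noninferiority analysis for
long-acting HIV therapy switch trials.

## What this package is for

Randomized switch trials compare long-acting injectable cabotegravir and
rilpivirine against continued daily oral antiretroviral therapy in people
who are already virally suppressed, under public-health monitoring (viral
load only every 24 weeks). Analyzing such a trial takes several tightly
coupled pieces of machinery that are usually buried in trial-specific SAS
or Stata code:

* a **modified FDA snapshot** classification of the week-96 outcome
  (suppressed / nonsuppressed / no virologic data from a weeks-84–102
  window, with temporary changes, oral bridging and within-class oral
  changes exempted from counting as treatment switches, and switches for
  virological failure assigned as nonsuppressed);
* derivation of the **ITT-exposed, per-protocol and complete-case**
  populations from dosing and disposition data (late unbridged injections,
  missed-oral-dose streaks, early withdrawal or death);
* detection of **confirmed virological failure** — two consecutive viral
  loads ≥200 copies/ml — under arm-specific retest rules, with explicit
  adjudication records for unconfirmable failures;
* **APOBEC-aware filtering** of baseline drug-resistance mutations: calls
  in the 14-item APOBEC-context set are disregarded when the carrying
  proviral sequence shows hypermutation evidence (signature mutations or
  stop codons);
* **noninferiority statistics** for risk differences: the
  Miettinen–Nurminen score interval with restricted-MLE variance and the
  N/(N−1) factor, its Cochran–Mantel–Haenszel-weighted stratified version,
  Wald intervals for safety tables, a homogeneity test for subgroups, and
  the standard sample-size formula.

The bounds of the MN interval are the values of δ where

    z(δ) = (p̂1 − p̂2 − δ) / sqrt{ [p̃1(1−p̃1)/n1 + p̃2(1−p̃2)/n2] · N/(N−1) }

equals ±z₀.₉₇₅, with (p̃1, p̃2) the MLEs restricted to p̃1 − p̃2 = δ
(closed-form cubic; bisection on a strictly decreasing score statistic).
Unlike the Wald interval it stays finite and positive-bounded at zero event
counts, which is exactly the situation a failure endpoint produces.

A seeded synthetic-trial generator (`generate_trial()`) and a deterministic
fixture (`make_fixture()`) supply data with the structure the analysis
assumes, so the whole pipeline is testable without access to
participant-level trial data.

## Worked example

```r
library(virosnap)

ds  <- make_fixture()          # deterministic 512-participant dataset
rep <- run_pipeline(ds)        # snapshot -> populations -> CVF -> stats
rep$snapshot
#>          arm suppressed nonsuppressed no_data   n
#>  long_acting        247             4       4 255
#>         oral        250             2       5 257
rep$populations$per_protocol
#> [1] 224 215
```

The failure endpoint with a zero count in the comparator arm:

```r
mn_score_ci(4, 255, 0, 257)
#> Risk difference (mn_score): 1.6 percentage points
#> 95% CI: 0.1 to 4.0
```

Read: switching carries a 1.6 percentage-point higher risk of confirmed
virological failure, with a 95% score interval from 0.1 to 4.0 — finite at
both ends despite the 0/257 arm. Against a +4 percentage-point
noninferiority margin the decision uses the upper bound
(`noninferiority_decision(ci, 4, "upper")`).

The design sample size for the suppression outcome (94% suppression both
arms, 10% margin, 5% two-sided alpha, 90% power):

```r
ni_sample_size(0.94, margin = 0.10)
#> [1] 119
```

A simulated trial instead of the fixture:

```r
ds <- generate_trial(sim_config(seed = 1))   # defaults: n = 512, 1:1
print(run_pipeline(ds))
```

## Layout

```
R/                    data model, I/O, snapshot, populations, virofail,
                      resistance filter, NI statistics, simulator, fixture,
                      pipeline
inst/extdata/         APOBEC-context DRM set (14 items) and small synthetic
                      DRM/signature lists for testing
inst/scripts/         thin command-line wrapper (generate | fixture | report)
tests/testthat/       unit, property and acceptance suites
scripts/acceptance.R  recomputes the reported interval bounds from scratch
```
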