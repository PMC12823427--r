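Package: virosnap
Title: Virologic Outcome Classification and Noninferiority Analysis for
    Long-Acting HIV Therapy Switch Trials
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Tools for the virologic-outcome analysis of randomized
    switch trials comparing long-acting injectable cabotegravir and
    rilpivirine with standard daily oral antiretroviral therapy under
    sparse viral-load monitoring. Implements a modified FDA snapshot
    classification of week-96 virologic outcome, derivation of
    intention-to-treat exposed, per-protocol and complete-case analysis
    populations from dosing and disposition data, detection of confirmed
    virological failure under arm-specific monitoring rules, filtering of
    baseline drug-resistance mutations that occur in an APOBEC
    hypermutation context, and stratified noninferiority statistics for
    risk differences (Miettinen-Nurminen score intervals, Cochran-
    Mantel-Haenszel weighted pooling, homogeneity testing, sample-size
    calculation). A seeded synthetic-trial generator and a deterministic
    outcome fixture allow every stage to be exercised without access to
    participant-level trial data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    seqinr
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse,
    jsonlite
Config/testthat/edition: 3
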