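Package: strooprel
Title: Reliability Analysis for Gamified Stroop Task Data
Version: 0.1.0
Authors@R:
    person("strooprel", "developers", email = "strooprel@example.org",
           role = c("aut", "cre"))
Description: Tools for estimating the psychometric reliability of
    Stroop interference costs from trial-level reaction-time data.
    Implements trial- and participant-level quality screening,
    per-condition performance summaries and interference-cost scoring,
    permutation-based split-half internal consistency with
    Spearman-Brown correction, Fisher-z comparison of independent
    correlations, Pearson and Shrout-Fleiss intraclass-correlation
    test-retest reliability, and reliability-versus-trial-count curves.
    Includes a hierarchical two-session cohort simulator with known
    ground-truth reliability (including a gamified points-scoring arm)
    plus closed-form oracles, and a reproducible end-to-end pipeline
    with CSV/JSON artifacts.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    data.table,
    jsonlite,
    yaml,
    Rcpp,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
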