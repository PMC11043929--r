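---
title: "Measuring the reliability of Stroop interference costs"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Measuring the reliability of Stroop interference costs}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(strooprel)
```

## The problem

The Stroop interference cost — the slowdown (or added errors) on
incongruent color-word trials relative to congruent trials — is one of the
most robust group-level effects in cognitive psychology, and one of the
least reliable person-level measurements. A difference of two within-person
means cancels the large, stable between-person variance in overall speed
and keeps only the much smaller variance in the interference effect itself,
so trial noise dominates. Any study that wants to rank people by their
Stroop effect (individual differences, clinical screening, or evaluating
whether gamified task variants change data quality) must therefore estimate
reliability explicitly: internal consistency within a session, and
test-retest stability across sessions.

`strooprel` packages the full workflow: screening, cost scoring,
permutation split-half consistency, Pearson/ICC test-retest, and
reliability-versus-trial-count curves, together with a simulator whose
ground-truth reliability is known in closed form, so every estimator in the
package can be validated against an analytic target.

## Data model

One row per trial: `participant_id`, `session` (1 or 2), `arm`
(`basic` or `game` — a between-subjects constant), `trial_index` (0-based
presentation order), `trial_type` (`congruent`, `neutral`, `incongruent`),
`correct` (0/1), `rt_ms` (> 0). The reference design is 240 trials per
condition, 720 per session, two sessions three weeks apart. CSVs are
UTF-8, comma-separated, header required, RTs serialized with at most three
decimals (so a write/read round trip is exact). Training trials are
assumed to be excluded upstream; the model does not represent them.

## Screening cascade

Web-collected RT data contain attention lapses the experimenter cannot
observe. The cascade runs in a fixed order:

1. **Both-sessions filter** — participants missing a session are dropped
   (test-retest needs both; configurable off).
2. **Per-trial trim** — within each participant-session, trials slower
   than the individual mean + 3 SD are removed (mean and sample SD over
   that participant-session's own trials, correct and incorrect alike).
3. **Absolute cap** — *remaining* trials slower than 2000 ms are removed.
   The cap deliberately sees only survivors of step 2, so every removed
   trial carries exactly one rule tag.
4. **Participant flags** — computed per session on the trimmed data:
   total incorrect count > group mean + 1 SD, or mean RT > group
   mean-of-means + 3 SD. A participant flagged at *either* session is
   excluded from both.

Decisions the procedure's usual description leaves open, and what this
package does: the error-count screen uses trimmed trials (configurable via
`flags_on_trimmed`); the 1 SD error threshold is applied per session with
exclusion on either, rather than pooled; sample (n−1) SDs are used
throughout; screening is one-shot, never iterated to a fixed point, so
re-screening already screened data can remove more (group statistics
change) — idempotence is deliberately *not* claimed. Every removal is
recorded in a ledger (`screening_report`) whose counts reconcile exactly:
kept + removed = input, enforced by tests.

Note that a 1 SD error screen is strict by construction: under a
homogeneous binomial error model roughly 15% of participants per session
sit above mean + 1 SD, so synthetic cohorts lose 25–35% of participants at
this stage. That is the stated rule, not a bug; real cohorts, with
overdispersed error counts, lose fewer.

## Scores

Per participant-session, from kept trials:

- `rt_cost` = mean RT(incongruent) − mean RT(congruent), correct trials
  only (standard Stroop practice; `rt_on_correct_only = FALSE` switches to
  all kept trials — the published-table arithmetic targets hold either
  way);
- `error_cost` = error %(incongruent) − error %(congruent), over all kept
  trials;
- the neutral condition is summarized but never enters a cost;
- distribution shape per participant-session via the adjusted
  Fisher–Pearson skewness G1 and sample excess kurtosis G2 (undefined and
  an error at zero spread; any consistent estimator satisfies the tests'
  symmetry and degenerate-case contracts).

## Internal consistency: permutation split-half

A single odd/even or first/second-half split is an arbitrary one-draw
estimate. The permutation approach repeats the split B times (default
5000): within each participant, each relevant condition's trials are
randomly partitioned into two halves (stratified by condition — a cost
needs both conditions in each half; odd counts send the extra trial to a
random half), the cost is computed per half, half-1 and half-2 costs are
Pearson-correlated across participants, and the correlation is projected
to full length with Spearman–Brown, r_SB = 2r/(1+r). We correct each
split, then average (the `average = "raw"` switch averages first and
corrects once); the 95% CI is the 2.5th/97.5th percentile of the B
corrected values, matching the percentile convention of the cited
permutation approach. Negative split correlations are corrected as-is —
no truncation at zero — so a corrected estimate can fall below −1;
truncation would bias near-zero reliabilities upward. Raw correlations
are clamped to [−1 + 1e−15, 1] purely to absorb floating-point excursions
(noise-free data can produce r = 1 + 2⁻⁵²). The B-split loop runs in
compiled code using R's own RNG stream, so results are reproducible with
`set.seed()`/`seed =` and invariant to input row order (trials are
canonically sorted before splitting).

## Test-retest: Pearson and ICCs

Pearson r between session-1 and session-2 costs, with
t = r√(n−2)/√(1−r²) on n−2 df and a Fisher-z CI
(atanh r ± 1.96/√(n−3); degenerate at |r| = 1, where the CI collapses to
the point). Independent correlations (e.g. basic vs game arm) are compared
with the Fisher z test, z = (atanh r₁ − atanh r₂)/√(1/(n₁−3) + 1/(n₂−3)),
two-sided.

Intraclass correlations follow Shrout & Fleiss's single-rater two-way
layout. From the n × k (participants × sessions) matrix: MSR (between
participants), MSC (between sessions), MSE (residual);

- consistency ICC(3,1) = (MSR − MSE) / (MSR + (k−1) MSE) — insensitive to
  a uniform session shift (practice effects);
- agreement ICC(2,1) = (MSR − MSE) / (MSR + (k−1) MSE + k (MSC − MSE)/n)
  — penalizes session mean shifts.

CIs use the Shrout–Fleiss F-based construction (Satterthwaite df for
ICC(2,1)). Incomplete matrices are an error — no imputation. The
implementation is validated property-style against an independent
`aov()`-based decomposition at 1e−10 on random matrices.

## Reliability as a function of trial count

`reliability_curve()` recomputes the score from only the first t kept
trials per condition (presentation order) in each session, then estimates
ICC(3,1) (or Pearson, via `estimator`) across sessions, for t on a grid
(default step 10, always including the full count). Participants with
fewer than t kept trials contribute all their kept trials rather than
being dropped: dropping would confound the curve with a changing n, which
is worse than a slightly conservative trial count; the per-point
`n_capped` column reports how many participants were short. The
per-trial-type variant tracks each condition's mean RT (or error rate)
instead of the cost. ICC(3,1) is the default estimator for uniformity
across all curves; a Pearson switch exists because the per-type variant is
sometimes reported that way.

## The synthetic cohort: a stated world

`generate_cohort()` simulates the two-arm, two-session design directly.
For subject i, session s:

- baseline a_is ~ bivariate normal across sessions, SD 90 ms,
  correlation 0.8;
- interference effect b_is = 110 + u_is, with u_is bivariate normal,
  SD 45 ms, correlation 0.7;
- condition means: congruent 660 + a_is, neutral 8 ms faster,
  incongruent adds b_is; the game arm is 30 ms faster at session 1 only;
- single-trial RTs are lognormal, moment-matched to the condition mean
  and a 150 ms trial SD — lognormal because empirical RT histograms are
  right-skewed and the support must be positive; a `trial_dist = "normal"`
  toggle exists for closed-form checks;
- with probability 0.03 (basic) / 0.015 (game) a trial is replaced by a
  lapse contaminant, uniform on 1400–2600 ms — the game arm's halved rate
  mirrors the reported pattern of fewer removed trials under gamification;
- correctness is Bernoulli per condition (error rates 4.5% congruent,
  3.5% neutral, 7% incongruent), independent of RT.

Calibration targets are the published descriptive statistics of a two-arm
gamified Stroop study (congruent means bracketed by 638–678 ms, RT costs
115–118 ms with SD ≈ 41–51 ms, percent correct 92–97%, a session-1-only
game speed advantage, and ~39% of removed trials falling in the game arm).
Where no value was stated (rho_baseline = 0.8, rho_effect = 0.7,
sigma_subject = 90 ms, sigma_trial = 150 ms, lapse window 1400–2600 ms)
values were chosen once at magnitudes typical for Stroop RT data — e.g.
rho_effect = 0.7 puts the n = 240 test-retest ICC near 0.64, inside the
0.48–0.66 band such studies report — and are not tuned afterwards.

What the generator does *not* emulate: practice/learning curves,
congruence-sequence (trial-to-trial adaptation) effects, within-trial
speed-accuracy coupling, condition-specific variance reduction in the game
arm (reported for incongruent trials; left as a possible extension,
default off), and overdispersed participant error counts. A green recovery
test therefore establishes that the estimators are correct *under this
model*, not that any particular empirical cohort will reach the same
reliability.

The gamified points rules are simulated exactly: +5 per correct answer,
−5 per incorrect answer, +25 when a correct response strictly beats the
running fastest-time record; the first correct response initializes the
record without a bonus, and incorrect responses never touch it. Strictness
and initialization are conventions of this package (the source rule text
says only that the record must be "broken") and are documented here
because they change hand-computed totals.

### Closed-form oracles

Because the model is linear in its random effects, the reliability of the
cost score is known analytically. With m trials per condition in a half,
the half-cost noise variance is 2σ²_trial/m, so the expected half-half
correlation is

    r_half(m) = σ²_effect / (σ²_effect + 2σ²_trial/m)

(`analytic_split_half_r`), and Spearman–Brown applied to r_half(m) equals
r_half(2m) — the correction and the model agree. The expected two-session
cost ICC(3,1) with n trials per condition is

    rho_effect · σ²_effect / (σ²_effect + 2σ²_trial/n)

(`analytic_retest_icc`). Both assume no lapse contaminants; the acceptance
suite generates 500-participant cohorts with `lapse_prob = 0` and requires
the estimators to land within ±0.05 of these targets (±0.07 across the
whole trial-count curve). The uncorrected mean split correlation is
compared to r_half(120) and the corrected point estimate to its
Spearman–Brown projection — corrected-vs-uncorrected would compare
different estimands.

## Numerical and degenerate-input choices

- Sample (n−1) SDs everywhere in screening.
- Fewer than 2 trials in a participant-session: trimming passes through
  with a warning (SD undefined). Single-participant cohorts: no
  participant flags, warning.
- Zero-variance sessions are an error for Pearson test-retest; identical
  ICC columns return exactly 1 with a degenerate CI.
- Split-half requires ≥ 2 trials per needed condition per participant
  (violators dropped with a warning) and ≥ 3 analyzable participants.
- Two-sided p-values throughout; no multiple-testing correction.
- The pipeline derives per-stage seeds from one global seed by fixed
  offsets, so each stage can be reproduced in isolation; identical config
  + seed gives byte-identical artifacts.

## Known limitations

Reliability coefficients from any one simulated cohort carry Monte-Carlo
error of order 1/√n; the acceptance tolerances are set accordingly and the
suite does not claim tighter recovery. The generator's independence of
correctness and RT means error-cost reliability is governed purely by the
binomial error rates, which understates the error-cost reliability real
speed-accuracy coupling can produce. The ICC confidence intervals are the
classical F-based ones; they are approximate for small n and exact only
under normality.
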