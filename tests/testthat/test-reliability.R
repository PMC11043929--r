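test_that("Spearman-Brown correction: values, monotonicity, domain", {
  expect_equal(spearman_brown(0), 0)
  expect_equal(spearman_brown(1), 1)
  expect_equal(spearman_brown(0.5), 2 / 3)
  expect_error(spearman_brown(-1), "undefined")
  expect_error(spearman_brown(1.2), "lie in")
  r <- seq(-0.99, 1, by = 0.01)
  expect_true(all(diff(spearman_brown(r)) > 0))
})

test_that("icc matches the brute-force two-way ANOVA oracle", {
  set.seed(314)
  for (i in 1:100) {
    m <- matrix(rnorm(10), nrow = 5, ncol = 2)
    expect_equal(icc(m, "icc31")$icc, icc_oracle(m, "icc31"),
                 tolerance = 1e-10)
    expect_equal(icc(m, "icc21")$icc, icc_oracle(m, "icc21"),
                 tolerance = 1e-10)
  }
})

test_that("icc degenerate geometry: identical columns and column shifts", {
  m <- cbind(c(1, 5, 9, 2), c(1, 5, 9, 2))
  expect_equal(icc(m, "icc31")$icc, 1)
  expect_equal(icc(m, "icc21")$icc, 1)

  shifted <- cbind(c(1, 5, 9, 2), c(1, 5, 9, 2) + 10)
  expect_equal(icc(shifted, "icc31")$icc, 1)
  expect_lt(icc(shifted, "icc21")$icc, 1)

  m42 <- matrix(c(1, 2, 3, 4, 5, 6, 8, 7), ncol = 2, byrow = TRUE)
  expect_equal(icc(m42, "icc31")$icc, icc_oracle(m42, "icc31"),
               tolerance = 1e-10)
  expect_equal(icc(m42, "icc21")$icc, icc_oracle(m42, "icc21"),
               tolerance = 1e-10)
  res <- icc(m42, "icc31")
  expect_true(res$ci_low <= res$icc && res$icc <= res$ci_high)

  expect_error(icc(matrix(c(1, 2, NA, 4, 5, 6), ncol = 2)), "complete")
  expect_error(icc(matrix(1:4, ncol = 2)), "n >= 3")
})

test_that("Fisher z comparison: identity, antisymmetry, published pair", {
  same <- compare_correlations_fisher(0.5, 30, 0.5, 40)
  expect_equal(same$z, 0)
  expect_equal(same$p, 1)

  a <- compare_correlations_fisher(0.78, 31, 0.83, 34)
  b <- compare_correlations_fisher(0.83, 34, 0.78, 31)
  expect_equal(a$z, -b$z)
  expect_lt(abs(a$z), 1.96)  # non-significant group difference
  expect_gt(a$p, 0.05)

  expect_error(compare_correlations_fisher(0.5, 3, 0.5, 30), "exceed 3")
  expect_error(compare_correlations_fisher(1, 30, 0.5, 30), "< 1")
})

test_that("Pearson test-retest: published t statistic and degenerate input", {
  # r = 0.68, n = 31 participants: t on 29 df near the printed 5.04
  set.seed(2718)
  x <- rnorm(31)
  target_r <- 0.68
  y0 <- target_r * scale(x) + sqrt(1 - target_r^2) * scale(rnorm(31))
  y <- as.numeric(y0)
  # force the sample correlation to be exactly 0.68 via residual rotation
  e <- residuals(lm(y ~ x))
  y <- target_r * scale(x) + sqrt(1 - target_r^2) * scale(e)
  est <- test_retest_pearson(x, as.numeric(y))
  expect_equal(est$point, 0.68, tolerance = 1e-10)
  expect_identical(est$df, 29L)
  expect_lt(abs(est$t - 5.04), 0.1)
  expect_true(est$ci_low <= est$point && est$point <= est$ci_high)

  ident <- test_retest_pearson(1:10, 1:10)
  expect_equal(ident$point, 1)
  expect_equal(c(ident$ci_low, ident$ci_high), c(1, 1))

  expect_error(test_retest_pearson(rep(1, 10), 1:10), "zero variance")
  expect_error(test_retest_pearson(1:3, 3:1), "at least 4")

  # null: independent sessions give r near 0 at large n
  set.seed(99)
  null_est <- test_retest_pearson(rnorm(5000), rnorm(5000))
  expect_lt(abs(null_est$point), 0.05)
})

test_that("split-half on a noise-free cohort is exactly 1", {
  p <- generator_params(n_per_arm = 12L, arms = "basic", sigma_trial = 0,
                        lapse_prob = 0,
                        error_rates = c(congruent = 0, neutral = 0,
                                        incongruent = 0),
                        plan = session_plan(n_per_condition = 20L,
                                            n_sessions = 1L),
                        seed = 8L)
  tr <- generate_cohort(p)$trials
  est <- permutation_split_half(tr, split_half_config(n_permutations = 50L,
                                                      seed = 1L))
  expect_equal(est$point, 1.0)
  expect_equal(est$raw_mean, 1.0)
})

test_that("split-half is seed-reproducible and row-order invariant", {
  co <- tiny_cohort(n = 8L, npc = 12L, sessions = 1L)
  cfg <- split_half_config(n_permutations = 40L, seed = 5L)
  e1 <- permutation_split_half(co$trials, cfg)
  e2 <- permutation_split_half(co$trials, cfg)
  expect_identical(e1, e2)

  set.seed(123)
  shuffled <- co$trials[sample(.N)]
  e3 <- permutation_split_half(shuffled, cfg)
  expect_identical(e1$point, e3$point)

  e4 <- permutation_split_half(co$trials,
                               split_half_config(n_permutations = 40L,
                                                 seed = 6L))
  expect_false(identical(e1$point, e4$point))
})

test_that("split-half input contracts", {
  co <- tiny_cohort(n = 2L, npc = 6L, sessions = 1L)
  expect_error(permutation_split_half(co$trials), "at least 3")
  two_sess <- tiny_cohort(n = 5L, npc = 6L)
  expect_error(permutation_split_half(two_sess$trials), "single session")

  # a participant with too few incongruent trials is dropped with warning
  co5 <- tiny_cohort(n = 5L, npc = 8L, sessions = 1L)
  tr <- co5$trials[!(participant_id == "b01" &
                       trial_type == "incongruent" & trial_index > 16)]
  expect_true(nrow(tr[participant_id == "b01" &
                        trial_type == "incongruent"]) < 2L)
  expect_warning(est <- permutation_split_half(
    tr, split_half_config(n_permutations = 20L, seed = 2L)), "dropped")
  expect_identical(est$n_participants, 4L)
})

test_that("error-cost split-half runs and stays in range", {
  co <- tiny_cohort(n = 10L, npc = 20L, sessions = 1L)
  est <- permutation_split_half(
    co$trials, split_half_config(n_permutations = 100L, seed = 4L,
                                 score = "error_cost"))
  expect_true(est$ci_low <= est$point && est$point <= est$ci_high)
  # SB-corrected estimates never exceed 1 (negative raw correlations may
  # correct below -1 by design; no truncation at 0)
  expect_true(est$point <= 1)
})

test_that("reliability curve: endpoint identity and noise-free constancy", {
  p <- generator_params(n_per_arm = 10L, arms = "basic", lapse_prob = 0,
                        plan = session_plan(n_per_condition = 30L),
                        seed = 13L)
  co <- generate_cohort(p)
  cv <- reliability_curve(co, metric = "cost", score = "rt_cost",
                          step = 10L)
  expect_identical(max(cv$t), 30L)
  costs <- strooprel:::participant_costs(co$trials)
  wide <- data.table::dcast(costs, participant_id ~ session,
                            value.var = "rt_cost")
  full <- icc(as.matrix(wide[, -1]), "icc31")$icc
  expect_equal(cv[t == 30L]$estimate, full, tolerance = 1e-12)

  nf <- generate_cohort(generator_params(
    n_per_arm = 6L, arms = "basic", sigma_trial = 0, lapse_prob = 0,
    error_rates = c(congruent = 0, neutral = 0, incongruent = 0),
    rho_effect = 1, rho_baseline = 1,
    plan = session_plan(n_per_condition = 20L), seed = 14L))
  cv_nf <- reliability_curve(nf, metric = "cost", step = 5L)
  expect_true(all(abs(cv_nf$estimate - 1) < 1e-12))
})

test_that("per-type curves produce one curve per trial type", {
  co <- tiny_cohort(n = 8L, npc = 12L)
  cv <- reliability_curve(co, metric = "per_type", step = 6L)
  expect_setequal(unique(cv$trial_type),
                  c("congruent", "neutral", "incongruent"))
  expect_true(all(cv$n_participants == 8L))
  cvp <- reliability_curve(co, metric = "cost", estimator = "pearson",
                           step = 6L)
  expect_true(all(is.finite(cvp$estimate)))
})

test_that("curves are non-decreasing in trial count on clean cohorts", {
  # Spearman correlation of (t, icc) averaged over seeds
  rho <- vapply(1:8, function(s) {
    co <- generate_cohort(generator_params(
      n_per_arm = 60L, arms = "basic", lapse_prob = 0,
      plan = session_plan(n_per_condition = 60L), seed = 100L + s))
    cv <- reliability_curve(co, metric = "cost", step = 10L)
    cor(cv$t, cv$estimate, method = "spearman")
  }, numeric(1))
  expect_gt(mean(rho), 0.9)
})
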