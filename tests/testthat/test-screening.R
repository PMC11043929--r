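test_that("per-trial trim follows the 3-SD-then-cap arithmetic", {
  rts <- c(400, 420, 410, 430, 405, 415, 425, 435, 410, 1900)
  tr <- make_trials(rt = rts)
  out <- trim_trials(tr, screening_config())
  thr <- mean(rts) + 3 * sd(rts)  # direct arithmetic oracle
  if (1900 > thr) {
    expect_identical(out$removed$rt_ms, 1900)
    expect_identical(out$removed$rule, "trial_sd")
  } else {
    expect_identical(nrow(out$removed), 0L)  # 1900 < 2000 cap
  }
  expect_identical(nrow(out$kept) + nrow(out$removed), nrow(tr))
})

test_that("cap rule catches slow trials that survive the 3-SD trim", {
  # wide spread so 2500 stays below mean + 3 SD but above the 2000 ms cap
  rts <- c(seq(300, 1900, by = 100), 2500)
  stopifnot(2500 <= mean(rts) + 3 * sd(rts))  # planted property
  out <- trim_trials(make_trials(rt = rts), screening_config())
  expect_identical(out$removed$rt_ms, 2500)
  expect_identical(out$removed$rule, "rt_cap")
})

test_that("degenerate trims: equal RTs keep everything, tiny groups pass through", {
  out <- trim_trials(make_trials(rt = rep(500, 10)), screening_config())
  expect_identical(nrow(out$removed), 0L)
  expect_warning(out1 <- trim_trials(make_trials(rt = 2500),
                                     screening_config()),
                 "< 2 trials")
  expect_identical(nrow(out1$removed), 0L)
})

test_that("participant error flag follows the 1-SD arithmetic", {
  # 10 participants, 100 trials each; nine with 20 errors, one with 80
  n_err <- c(rep(20L, 9), 80L)
  rows <- lapply(seq_along(n_err), function(i) {
    make_trials(pid = sprintf("p%02d", i),
                correct = rep(c(0L, 1L), c(n_err[i], 100L - n_err[i])),
                rt = 500)
  })
  tr <- do.call(rbind, rows)
  flags <- flag_participants(tr, screening_config())
  thr <- mean(n_err) + 1 * sd(n_err)  # direct arithmetic oracle
  if (80 > thr) {
    expect_identical(flags$participant_id, "p10")
    expect_identical(flags$rule, "high_errors")
  } else {
    expect_identical(nrow(flags), 0L)
  }
})

test_that("identical participants raise no flags; singletons warn", {
  tr <- rbind(make_trials(pid = "a", rt = rep(c(400, 600), 10)),
              make_trials(pid = "b", rt = rep(c(400, 600), 10)))
  expect_identical(nrow(flag_participants(tr, screening_config())), 0L)
  expect_warning(f1 <- flag_participants(make_trials(rt = rep(500, 5)),
                                         screening_config()),
                 "fewer than 2 participants")
  expect_identical(nrow(f1), 0L)
})

test_that("a participant flagged at one session is excluded from both", {
  mk <- function(pid, s, correct) {
    make_trials(pid = pid, session = s, correct = correct,
                rt = seq(400, 590, by = 10))
  }
  good <- c(rep(1L, 19), 0L)
  bad <- rep(0L, 20)
  tr <- rbind(mk("a", 1L, good), mk("a", 2L, good),
              mk("b", 1L, good), mk("b", 2L, good),
              mk("c", 1L, good), mk("c", 2L, good),
              mk("d", 1L, good), mk("d", 2L, bad))  # flagged at session 2 only
  scr <- apply_screening(as_cohort(tr, session_plan(n_per_condition = 20L)),
                         screening_config())
  expect_identical(sort(scr$report$excluded_participant_ids), "d")
  expect_false("d" %in% scr$cohort$trials$participant_id)
  expect_true(all(scr$report$excluded_participants$session == 2L))
})

test_that("planted fixture: cap trial, 3-SD trial, and high-error participant", {
  # wide deterministic spread: mean + 3 SD of c(base, 2500) is ~2900, so a
  # planted 2500 ms trial survives the 3-SD trim and falls to the cap rule,
  # while a planted 12000 ms trial exceeds mean + 3 SD and is trimmed
  base <- seq(300, 1900, by = 100)  # 17 trials, all below the 2000 ms cap
  one_err <- rep(c(0L, 1L), c(1L, 16L))
  mk <- function(pid, rt = base, correct = c(one_err, 1L)[seq_along(rt)],
                 plant = NULL) {
    if (identical(plant, "cap")) rt <- c(rt, 2500)
    if (identical(plant, "sd")) rt <- c(rt, 12000)
    if (identical(plant, "errors")) correct <- rep(0L, length(rt))
    stopifnot(length(correct) == length(rt))
    make_trials(pid = pid, correct = correct, rt = rt)
  }
  stopifnot(2500 <= mean(c(base, 2500)) + 3 * sd(c(base, 2500)),
            12000 > mean(c(base, 12000)) + 3 * sd(c(base, 12000)))
  tr <- rbind(mk("ok1"), mk("ok2"), mk("ok3"), mk("ok4"), mk("ok5"),
              mk("cap1", plant = "cap"), mk("sd1", plant = "sd"),
              mk("err1", plant = "errors"))
  cohort <- as_cohort(tr, session_plan(n_per_condition = 6L,
                                       n_sessions = 1L))
  scr <- apply_screening(cohort,
                         screening_config(require_both_sessions = FALSE))
  rep_ <- scr$report

  expect_identical(rep_$removed_trials_total_by_rule[rule == "rt_cap"]$n, 1L)
  expect_identical(rep_$removed_trials_total_by_rule[rule == "trial_sd"]$n, 1L)
  expect_identical(
    rep_$removed_trials[rule == "rt_cap"]$participant_id, "cap1")
  expect_identical(
    rep_$removed_trials[rule == "trial_sd"]$participant_id, "sd1")
  expect_identical(rep_$excluded_participant_ids, "err1")
  expect_identical(rep_$excluded_participants$rule, "high_errors")
  # conservation
  expect_identical(rep_$n_trials_kept,
                   rep_$n_trials_input - rep_$n_trials_trimmed -
                     rep_$n_trials_removed_with_excluded)
})

test_that("conservation holds per participant-session on random cohorts", {
  co <- generate_cohort(generator_params(n_per_arm = 6L, seed = 77L))
  out <- trim_trials(co$trials, screening_config())
  n_in <- co$trials[, .N, by = c("participant_id", "session")]
  n_kept <- out$kept[, .N, by = c("participant_id", "session")]
  n_rem <- out$removed[, .N, by = c("participant_id", "session")]
  merged <- merge(n_in, n_kept, by = c("participant_id", "session"),
                  suffixes = c("_in", "_kept"))
  merged <- merge(merged, n_rem, by = c("participant_id", "session"),
                  all.x = TRUE)
  merged[is.na(N), N := 0L]
  expect_true(all(merged$N_in == merged$N_kept + merged$N))
})

test_that("looser thresholds never remove more trials", {
  co <- generate_cohort(generator_params(n_per_arm = 6L, seed = 78L))
  n_removed <- function(k, cap) {
    nrow(trim_trials(co$trials,
                     screening_config(trial_sd_k = k, rt_cap_ms = cap))$removed)
  }
  expect_true(n_removed(2, 2000) >= n_removed(3, 2000))
  expect_true(n_removed(3, 2000) >= n_removed(4, 2000))
  expect_true(n_removed(3, 1500) >= n_removed(3, 2000))
  expect_true(n_removed(3, 2000) >= n_removed(3, 3000))
})

test_that("both-sessions requirement drops incomplete participants", {
  tr <- rbind(make_trials(pid = "a", session = 1L, rt = seq(400, 500, 20)),
              make_trials(pid = "a", session = 2L, rt = seq(400, 500, 20)),
              make_trials(pid = "b", session = 1L, rt = seq(400, 500, 20)))
  co <- as_cohort(tr, session_plan(n_per_condition = 2L))
  scr <- apply_screening(co, screening_config())
  expect_identical(scr$report$incomplete_participants, "b")
  expect_false("b" %in% scr$cohort$trials$participant_id)
  scr2 <- apply_screening(co, screening_config(require_both_sessions = FALSE))
  expect_true("b" %in% scr2$cohort$trials$participant_id)
})
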