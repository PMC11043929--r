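# Exclusion cascade: both-sessions filter -> per-trial 3-SD trim ->
# 2000 ms cap -> participant error/slow-responder flags, with a full
# audit ledger.

#' Screening configuration
#'
#' Thresholds for the trial- and participant-level exclusion cascade:
#' within each participant-session, trials slower than the individual mean
#' plus `trial_sd_k` SDs are removed, then any remaining trials slower
#' than `rt_cap_ms`; afterwards, participants whose total incorrect count
#' exceeds the group mean by more than `error_sd_k` SDs, or whose mean RT
#' exceeds the group mean-of-means by more than `slow_participant_sd_k`
#' SDs, at either session, are excluded entirely.
#'
#' @param trial_sd_k Per-trial slow-outlier threshold in SDs (default 3).
#' @param rt_cap_ms Absolute RT cap in milliseconds (default 2000).
#' @param error_sd_k Participant incorrect-count threshold in SDs (default 1).
#' @param slow_participant_sd_k Participant mean-RT threshold in SDs
#'   (default 3).
#' @param require_both_sessions Drop participants missing a session
#'   (default `TRUE`).
#' @param flags_on_trimmed Compute participant flags on trimmed trials
#'   (default `TRUE`); set `FALSE` to use raw trials for the error count.
#' @return An object of class `screening_config`.
#' @export
screening_config <- function(trial_sd_k = 3, rt_cap_ms = 2000,
                             error_sd_k = 1, slow_participant_sd_k = 3,
                             require_both_sessions = TRUE,
                             flags_on_trimmed = TRUE) {
  if (any(c(trial_sd_k, error_sd_k, slow_participant_sd_k) <= 0) ||
      rt_cap_ms <= 0)
    stop("all screening thresholds must be positive", call. = FALSE)
  structure(list(trial_sd_k = trial_sd_k, rt_cap_ms = rt_cap_ms,
                 error_sd_k = error_sd_k,
                 slow_participant_sd_k = slow_participant_sd_k,
                 require_both_sessions = isTRUE(require_both_sessions),
                 flags_on_trimmed = isTRUE(flags_on_trimmed)),
            class = "screening_config")
}

#' Trim slow outlier trials within each participant-session
#'
#' Two-step per-trial trim. Step 1 removes trials with
#' `rt > mean + trial_sd_k * SD`, where mean and sample SD are computed
#' over that participant-session's own trials (correct and incorrect
#' alike). Step 2 removes *remaining* trials slower than `rt_cap_ms`; the
#' cap deliberately applies only to survivors of step 1, so each removed
#' trial carries a single rule tag. Groups with fewer than 2 trials pass
#' through with a warning (SD undefined).
#'
#' @param trials A data.table/data.frame of trials (any number of
#'   participant-sessions).
#' @param cfg A [screening_config()].
#' @return A list with `kept` (trials minus removals) and `removed`
#'   (removed trials with an extra `rule` column: "trial_sd" or "rt_cap").
#' @export
trim_trials <- function(trials, cfg = screening_config()) {
  stopifnot(inherits(cfg, "screening_config"))
  tr <- data.table::as.data.table(trials)
  if (nrow(tr) == 0L)
    return(list(kept = tr, removed = data.table::copy(tr)[, rule := character(0)]))

  tr[, `:=`(.mu = mean(rt_ms), .sd = stats::sd(rt_ms), .n = .N),
     by = c("participant_id", "session")]
  if (any(tr$.n < 2L))
    warning("participant-session(s) with < 2 trials passed through untrimmed",
            call. = FALSE)
  hit <- rep(NA_character_, nrow(tr))
  sd_ok <- tr$.n >= 2L & !is.na(tr$.sd) & tr$.sd > 0
  hit_sd <- sd_ok & tr$rt_ms > tr$.mu + cfg$trial_sd_k * tr$.sd
  hit[hit_sd] <- "trial_sd"
  hit_cap <- !hit_sd & tr$.n >= 2L & tr$rt_ms > cfg$rt_cap_ms
  hit[hit_cap] <- "rt_cap"
  tr[, c(".mu", ".sd", ".n") := NULL]
  tr[, rule := hit]

  removed <- tr[!is.na(rule)]
  kept <- tr[is.na(rule)]
  kept[, rule := NULL]
  list(kept = kept, removed = removed)
}

#' Flag participants for exclusion
#'
#' Computed per session on (by default) trimmed trials: a participant is
#' flagged if their total incorrect count exceeds the session's group mean
#' by more than `error_sd_k` sample SDs, or if their mean RT exceeds the
#' session's group mean-of-participant-means by more than
#' `slow_participant_sd_k` SDs. A participant flagged at either session is
#' excluded from both.
#'
#' @param trials Trimmed trials (all participants, all sessions).
#' @param cfg A [screening_config()].
#' @return A data.table with columns `participant_id`, `session`, `rule`
#'   ("high_errors" or "slow_mean_rt"), one row per flag raised; zero rows
#'   when no one is flagged.
#' @export
flag_participants <- function(trials, cfg = screening_config()) {
  stopifnot(inherits(cfg, "screening_config"))
  tr <- data.table::as.data.table(trials)
  empty <- data.table::data.table(participant_id = character(0),
                                  session = integer(0), rule = character(0))
  if (nrow(tr) == 0L) return(empty)

  per <- tr[, list(n_incorrect = sum(correct == 0L), mean_rt = mean(rt_ms)),
            by = c("participant_id", "session")]
  if (data.table::uniqueN(per$participant_id) < 2L) {
    warning("fewer than 2 participants: no participant-level exclusions",
            call. = FALSE)
    return(empty)
  }
  per[, `:=`(err_thr = mean(n_incorrect) + cfg$error_sd_k * stats::sd(n_incorrect),
             rt_thr = mean(mean_rt) + cfg$slow_participant_sd_k * stats::sd(mean_rt)),
      by = "session"]
  flags <- data.table::rbindlist(list(
    per[!is.na(err_thr) & n_incorrect > err_thr,
        list(participant_id, session, rule = "high_errors")],
    per[!is.na(rt_thr) & mean_rt > rt_thr,
        list(participant_id, session, rule = "slow_mean_rt")]))
  if (nrow(flags) == 0L) empty else flags[order(participant_id, session)]
}

#' Apply the full screening cascade
#'
#' Runs, in order: (1) drop participants lacking any session of the plan
#' (if `require_both_sessions`); (2) per-trial slow-outlier trim
#' ([trim_trials()]); (3) participant flags on the trimmed data
#' ([flag_participants()]), removing flagged participants from all
#' sessions. Screening is one-shot: thresholds are not recomputed after
#' exclusions, so re-screening an already screened cohort can in principle
#' remove more data (group statistics change) and idempotence is not
#' guaranteed.
#'
#' @param cohort A `stroop_cohort`.
#' @param cfg A [screening_config()].
#' @return A list with `cohort` (a `stroop_cohort` of kept trials, class
#'   also `screened_cohort`) and `report` (a `screening_report`).
#' @export
apply_screening <- function(cohort, cfg = screening_config()) {
  stopifnot(inherits(cohort, "stroop_cohort"), inherits(cfg, "screening_config"))
  tr <- data.table::copy(cohort$trials)
  n_input <- nrow(tr)

  # stage 1: both-sessions filter
  incomplete <- character(0)
  if (cfg$require_both_sessions && n_input > 0L) {
    sess_n <- tr[, list(n_sessions = data.table::uniqueN(session)),
                 by = "participant_id"]
    incomplete <- sess_n[n_sessions < cohort$plan$n_sessions]$participant_id
    tr <- tr[!participant_id %in% incomplete]
  }
  n_after_complete <- nrow(tr)

  # stage 2: per-trial trim
  trimmed <- trim_trials(tr, cfg)

  # stage 3: participant flags on trimmed data (error screen optionally raw)
  flag_input <- if (cfg$flags_on_trimmed) trimmed$kept else tr
  flags <- if (nrow(trimmed$kept) > 0L) flag_participants(flag_input, cfg)
           else flag_participants(trimmed$kept, cfg)
  excluded_ids <- unique(flags$participant_id)
  kept <- trimmed$kept[!participant_id %in% excluded_ids]

  removed_by_rule <- if (nrow(trimmed$removed) > 0L) {
    trimmed$removed[, list(n = .N), by = c("participant_id", "session", "rule")]
  } else {
    data.table::data.table(participant_id = character(0),
                           session = integer(0), rule = character(0),
                           n = integer(0))
  }

  report <- structure(list(
    n_trials_input = n_input,
    n_trials_after_session_filter = n_after_complete,
    n_trials_trimmed = nrow(trimmed$removed),
    n_trials_removed_with_excluded = nrow(trimmed$kept) - nrow(kept),
    n_trials_kept = nrow(kept),
    incomplete_participants = incomplete,
    removed_trials = removed_by_rule,
    removed_trials_total_by_rule =
      if (nrow(trimmed$removed) > 0L)
        trimmed$removed[, list(n = .N), by = "rule"]
      else data.table::data.table(rule = character(0), n = integer(0)),
    excluded_participants = flags,
    excluded_participant_ids = excluded_ids,
    config = cfg), class = "screening_report")

  screened <- structure(list(trials = kept, plan = cohort$plan),
                        class = c("screened_cohort", "stroop_cohort"))
  list(cohort = screened, report = report)
}

#' @export
print.screening_report <- function(x, ...) {
  cat("Screening report\n")
  cat(sprintf("  input trials:                 %d\n", x$n_trials_input))
  cat(sprintf("  dropped (incomplete sessions): %d participants\n",
              length(x$incomplete_participants)))
  cat(sprintf("  trials trimmed:               %d\n", x$n_trials_trimmed))
  if (nrow(x$removed_trials_total_by_rule) > 0L)
    for (i in seq_len(nrow(x$removed_trials_total_by_rule)))
      cat(sprintf("    rule %-10s %d\n",
                  x$removed_trials_total_by_rule$rule[i],
                  x$removed_trials_total_by_rule$n[i]))
  cat(sprintf("  participants excluded:        %d (%s)\n",
              length(x$excluded_participant_ids),
              paste(utils::head(x$excluded_participant_ids, 8L),
                    collapse = ", ")))
  cat(sprintf("  trials kept:                  %d\n", x$n_trials_kept))
  invisible(x)
}
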