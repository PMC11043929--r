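# Trial-level data model and CSV I/O for two-session Stroop cohorts.

TRIAL_TYPES <- c("congruent", "neutral", "incongruent")
ARMS <- c("basic", "game")
TRIAL_COLUMNS <- c("participant_id", "session", "arm", "trial_index",
                   "trial_type", "correct", "rt_ms")

#' Session plan for a Stroop cohort
#'
#' Describes the design of one testing session: how many trials of each
#' trial type (congruent, neutral, incongruent) a session contains, and how
#' many sessions the cohort has. The default plan is 240 trials per
#' condition (720 per session) over two sessions.
#'
#' @param n_per_condition Trials per trial type within one session.
#' @param n_sessions Number of testing sessions per participant.
#' @return An object of class `session_plan`.
#' @examples
#' plan <- session_plan()
#' plan$n_per_condition * length(plan$conditions)  # 720 trials per session
#' @export
session_plan <- function(n_per_condition = 240L, n_sessions = 2L) {
  n_per_condition <- as.integer(n_per_condition)
  n_sessions <- as.integer(n_sessions)
  if (is.na(n_per_condition) || n_per_condition < 1L)
    stop("n_per_condition must be a positive integer", call. = FALSE)
  if (is.na(n_sessions) || n_sessions < 1L)
    stop("n_sessions must be a positive integer", call. = FALSE)
  structure(
    list(n_per_condition = n_per_condition,
         conditions = TRIAL_TYPES,
         n_sessions = n_sessions),
    class = "session_plan")
}

#' @export
print.session_plan <- function(x, ...) {
  cat(sprintf("Session plan: %d sessions x %d trials (%d per condition: %s)\n",
              x$n_sessions, x$n_per_condition * length(x$conditions),
              x$n_per_condition, paste(x$conditions, collapse = ", ")))
  invisible(x)
}

#' Construct a cohort from a trial table
#'
#' Validates a table of trial records and wraps it, together with a
#' [session_plan()], into a `stroop_cohort`. One row is one
#' stimulus-response event. Required columns: `participant_id`, `session`,
#' `arm` ("basic"/"game"), `trial_type`
#' ("congruent"/"neutral"/"incongruent"), `correct` (0/1 or logical), and
#' `rt_ms` (positive reaction time in milliseconds). `trial_index`
#' (0-based presentation order within a participant-session) is assigned
#' from row order when absent.
#'
#' @param trials A data.frame of trial records.
#' @param plan A [session_plan()]; defaults to the standard 240 x 3 x 2 design.
#' @param strict If `TRUE` (default) invalid rows are an error; otherwise
#'   they are dropped with a warning.
#' @return A `stroop_cohort`: list with elements `trials` (a data.table)
#'   and `plan`.
#' @export
as_cohort <- function(trials, plan = session_plan(), strict = TRUE) {
  trials <- data.table::as.data.table(trials)
  missing_cols <- setdiff(setdiff(TRIAL_COLUMNS, "trial_index"),
                          names(trials))
  if (length(missing_cols) > 0L)
    stop("missing required column(s): ", paste(missing_cols, collapse = ", "),
         call. = FALSE)

  trials[, participant_id := as.character(participant_id)]
  trials[, session := as.integer(session)]
  trials[, arm := as.character(arm)]
  trials[, trial_type := as.character(trial_type)]
  trials[, correct := as.integer(as.logical(as.integer(correct)))]
  trials[, rt_ms := as.numeric(rt_ms)]

  bad <- which(is.na(trials$rt_ms) | trials$rt_ms <= 0 |
               !(trials$trial_type %in% TRIAL_TYPES) |
               !(trials$arm %in% ARMS) |
               is.na(trials$correct) | is.na(trials$session))
  if (length(bad) > 0L) {
    if (strict)
      stop(sprintf("invalid trial row(s): %s (non-positive rt_ms, unknown trial_type/arm, or missing value)",
                   paste(utils::head(bad, 5L), collapse = ", ")),
           call. = FALSE)
    warning(sprintf("dropping %d invalid trial row(s)", length(bad)),
            call. = FALSE)
    trials <- trials[-bad]
  }

  # arm is a participant-level constant in a between-subjects design
  arm_check <- trials[, list(n_arms = data.table::uniqueN(arm)),
                      by = "participant_id"]
  if (any(arm_check$n_arms > 1L))
    stop("participant(s) with conflicting arm labels: ",
         paste(utils::head(arm_check[n_arms > 1L]$participant_id, 5L),
               collapse = ", "), call. = FALSE)

  if (!("trial_index" %in% names(trials))) {
    trials[, trial_index := seq_len(.N) - 1L, by = c("participant_id", "session")]
  } else {
    trials[, trial_index := as.integer(trial_index)]
    dup <- trials[, list(dup = anyDuplicated(trial_index) > 0L),
                  by = c("participant_id", "session")]
    if (any(dup$dup))
      stop("duplicated trial_index within a participant-session", call. = FALSE)
  }
  data.table::setorderv(trials, c("participant_id", "session", "trial_index"))
  data.table::setcolorder(trials, TRIAL_COLUMNS)

  structure(list(trials = trials[], plan = plan), class = "stroop_cohort")
}

#' @export
print.stroop_cohort <- function(x, ...) {
  tr <- x$trials
  cat(sprintf("Stroop cohort: %d participants, %d sessions, %d trials\n",
              data.table::uniqueN(tr$participant_id),
              data.table::uniqueN(tr$session), nrow(tr)))
  arm_n <- tr[, list(n = data.table::uniqueN(participant_id)), by = "arm"]
  cat("  arms:", paste(sprintf("%s (n=%d)", arm_n$arm, arm_n$n),
                       collapse = ", "), "\n")
  invisible(x)
}

#' Read trial-level data from CSV
#'
#' Reads a trial CSV (UTF-8, comma-separated, header required) with columns
#' `participant_id, session, arm, trial_index, trial_type, correct, rt_ms`
#' (`correct` encoded 0/1). When `trial_index` is absent, presentation
#' order is taken from row order.
#'
#' @param path Path to a CSV file.
#' @param strict If `TRUE`, rows violating the schema (non-positive RT,
#'   unknown trial type) are an error; otherwise they are dropped with a
#'   warning.
#' @param plan Session plan attached to the cohort.
#' @return A `stroop_cohort`.
#' @seealso [write_trials()]
#' @export
read_trials <- function(path, strict = TRUE, plan = session_plan()) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  trials <- data.table::fread(path, sep = ",", header = TRUE,
                              colClasses = list(character = "participant_id"),
                              encoding = "UTF-8", showProgress = FALSE)
  as_cohort(trials, plan = plan, strict = strict)
}

#' Write trial-level data to CSV
#'
#' Serializes a cohort to the standard trial CSV. Reaction times are
#' written in milliseconds with at most 3 decimal places, so that a
#' read/write round trip reproduces every field exactly. An empty cohort
#' yields a header-only file.
#'
#' @param cohort A `stroop_cohort`.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_trials <- function(cohort, path) {
  stopifnot(inherits(cohort, "stroop_cohort"))
  out <- data.table::copy(cohort$trials)
  out[, rt_ms := round(rt_ms, 3)]
  data.table::fwrite(out, path, sep = ",", quote = FALSE)
  invisible(path)
}
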