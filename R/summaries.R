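# Per-participant-session condition summaries, interference costs, and
# RT distribution shape.

#' Summarize one participant-session by trial type
#'
#' Computes, for each trial type present, the mean reaction time (over
#' correct trials only by default), percent correct (over all kept trials
#' of that type), and trial counts. A trial type with zero correct trials
#' gets `mean_rt = NA` (flagged, not an error).
#'
#' @param trials Trials of one participant-session (screened).
#' @param rt_on_correct_only If `TRUE` (default, standard Stroop practice)
#'   RT means use correct trials only; if `FALSE`, all kept trials.
#' @return A `condition_summary`: data.table with columns `trial_type`,
#'   `n`, `n_correct`, `pct_correct`, `mean_rt`.
#' @export
summarize_conditions <- function(trials, rt_on_correct_only = TRUE) {
  tr <- data.table::as.data.table(trials)
  if (nrow(tr) == 0L) stop("no trials to summarize", call. = FALSE)
  out <- tr[, {
    rts <- if (rt_on_correct_only) rt_ms[correct == 1L] else rt_ms
    list(n = .N,
         n_correct = sum(correct == 1L),
         pct_correct = 100 * sum(correct == 1L) / .N,
         mean_rt = if (length(rts) > 0L) mean(rts) else NA_real_)
  }, by = "trial_type"]
  out[, trial_type := factor(trial_type, levels = TRIAL_TYPES)]
  data.table::setorderv(out, "trial_type")
  out[, trial_type := as.character(trial_type)]
  data.table::setattr(out, "class",
                      c("condition_summary", class(out)))
  out[]
}

#' Construct a condition summary from known values
#'
#' Builds a `condition_summary` directly from per-condition means, e.g. to
#' apply the cost definition to published descriptive statistics.
#'
#' @param trial_type Character vector of trial types.
#' @param mean_rt Mean RT (ms) per type.
#' @param pct_correct Percent correct per type (default `NA`).
#' @param n Trial count per type (default `NA`).
#' @return A `condition_summary`.
#' @examples
#' s <- condition_summary(c("congruent", "incongruent"),
#'                        mean_rt = c(678, 796),
#'                        pct_correct = c(96.0, 93.1))
#' cost_scores(s)$rt_cost  # 118
#' @export
condition_summary <- function(trial_type, mean_rt,
                              pct_correct = NA_real_, n = NA_integer_) {
  if (!all(trial_type %in% TRIAL_TYPES))
    stop("unknown trial_type", call. = FALSE)
  out <- data.table::data.table(
    trial_type = trial_type, n = as.integer(n),
    n_correct = NA_integer_,
    pct_correct = as.numeric(pct_correct), mean_rt = as.numeric(mean_rt))
  data.table::setattr(out, "class", c("condition_summary", class(out)))
  out[]
}

#' Interference (Stroop) cost scores
#'
#' The per-person Stroop effect magnitude: `rt_cost` is the incongruent
#' mean RT minus the congruent mean RT (milliseconds); `error_cost` is the
#' incongruent error percentage minus the congruent error percentage
#' (percentage points). The neutral condition never enters the costs.
#'
#' @param summary A `condition_summary` containing both the congruent and
#'   incongruent rows.
#' @return A list with `rt_cost` and `error_cost` (either may be `NA` if
#'   the needed inputs are missing in the summary).
#' @export
cost_scores <- function(summary) {
  stopifnot(inherits(summary, "condition_summary"))
  need <- c("congruent", "incongruent")
  if (!all(need %in% summary$trial_type))
    stop("summary must contain congruent and incongruent rows", call. = FALSE)
  cong <- summary[summary$trial_type == "congruent", ]
  inc <- summary[summary$trial_type == "incongruent", ]
  list(rt_cost = inc$mean_rt - cong$mean_rt,
       error_cost = (100 - inc$pct_correct) - (100 - cong$pct_correct))
}

#' Skewness and excess kurtosis of a reaction-time distribution
#'
#' Adjusted Fisher-Pearson standardized moment coefficient
#' G1 = g1 * sqrt(n(n-1)) / (n-2) with g1 = m3 / m2^(3/2), and
#' sample excess kurtosis
#' G2 = ((n+1) g2 + 6) (n-1) / ((n-2)(n-3)) with g2 = m4 / m2^2 - 3,
#' where m_k are central sample moments. Requires at least 3 observations
#' (4 for kurtosis, else `NA`) and positive spread.
#'
#' @param x Numeric vector of reaction times (one participant-session).
#' @return A list with `skewness` and `excess_kurtosis`.
#' @export
shape_stats <- function(x) {
  x <- as.numeric(x)
  n <- length(x)
  if (n < 3L) stop("need at least 3 observations", call. = FALSE)
  m <- mean(x)
  m2 <- mean((x - m)^2)
  if (m2 == 0) stop("zero variance: shape statistics undefined", call. = FALSE)
  g1 <- mean((x - m)^3) / m2^1.5
  G1 <- g1 * sqrt(n * (n - 1)) / (n - 2)
  G2 <- if (n >= 4L) {
    g2 <- mean((x - m)^4) / m2^2 - 3
    ((n + 1) * g2 + 6) * (n - 1) / ((n - 2) * (n - 3))
  } else NA_real_
  list(skewness = G1, excess_kurtosis = G2)
}

# Per-participant-session cost scores for a whole cohort: one row per
# (participant_id, session, arm) with rt_cost and error_cost.
participant_costs <- function(trials, rt_on_correct_only = TRUE) {
  tr <- data.table::as.data.table(trials)
  tr[, {
    s <- summarize_conditions(.SD, rt_on_correct_only = rt_on_correct_only)
    cs <- cost_scores(s)
    list(rt_cost = cs$rt_cost, error_cost = cs$error_cost)
  }, by = c("participant_id", "session", "arm")]
}

#' Cohort-level descriptive cost table
#'
#' Per arm and session: means and SDs (across participants) of the
#' per-condition mean RTs, percent correct, and the RT and error-rate
#' costs — the layout of a standard descriptive-statistics table for a
#' two-arm, two-session Stroop study.
#'
#' @param cohort A screened `stroop_cohort` (or bare trial table).
#' @param rt_on_correct_only Passed to [summarize_conditions()].
#' @return A data.table with columns `arm`, `session`, `measure`, `mean`,
#'   `sd`, `n_participants`. SDs are `NA` for single-participant cells.
#' @export
cohort_cost_table <- function(cohort, rt_on_correct_only = TRUE) {
  tr <- if (inherits(cohort, "stroop_cohort")) cohort$trials
        else data.table::as.data.table(cohort)
  if (nrow(tr) == 0L) stop("empty cohort", call. = FALSE)

  per <- tr[, {
    s <- summarize_conditions(.SD, rt_on_correct_only = rt_on_correct_only)
    cs <- cost_scores(s)
    vals <- c(stats::setNames(s$mean_rt, paste0(s$trial_type, "_rt")),
              stats::setNames(s$pct_correct, paste0(s$trial_type, "_pct_correct")),
              rt_cost = cs$rt_cost, error_cost = cs$error_cost)
    as.list(vals)
  }, by = c("participant_id", "session", "arm")]

  measures <- setdiff(names(per), c("participant_id", "session", "arm"))
  long <- data.table::melt(per, id.vars = c("participant_id", "session", "arm"),
                           measure.vars = measures,
                           variable.name = "measure", value.name = "value")
  out <- long[, list(mean = mean(value, na.rm = TRUE),
                     sd = stats::sd(value[!is.na(value)]),
                     n_participants = sum(!is.na(value))),
              by = c("arm", "session", "measure")]
  out[, measure := as.character(measure)]
  data.table::setorderv(out, c("arm", "session", "measure"))
  out[]
}
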