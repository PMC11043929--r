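# Reliability estimators: permutation split-half with Spearman-Brown
# correction, Fisher-z comparison of independent correlations, Pearson
# test-retest, Shrout-Fleiss ICCs, and reliability-vs-trial-count curves.

#' Spearman-Brown prophecy correction
#'
#' Projects a half-test correlation to full-test reliability:
#' `r_full = 2 r / (1 + r)`. Monotone increasing on (-1, 1]; undefined at
#' r = -1. Negative inputs are corrected as-is (no truncation at 0).
#'
#' @param r Half-half correlation(s) in (-1, 1].
#' @return Corrected reliability, same length as `r`.
#' @export
spearman_brown <- function(r) {
  r <- as.numeric(r)
  if (any(!is.na(r) & abs(r) > 1)) stop("r must lie in [-1, 1]", call. = FALSE)
  if (any(!is.na(r) & r == -1))
    stop("Spearman-Brown correction is undefined at r = -1", call. = FALSE)
  2 * r / (1 + r)
}

#' Split-half configuration
#'
#' @param n_permutations Number of random splits B (default 5000).
#' @param seed Integer seed for the split RNG, or `NULL`.
#' @param score "rt_cost" (RT interference cost, on correct trials) or
#'   "error_cost" (error-percentage cost, on all kept trials).
#' @param average "corrected" (default: Spearman-Brown per split, then
#'   average) or "raw" (average raw split correlations, then correct once).
#' @return An object of class `split_half_config`.
#' @export
split_half_config <- function(n_permutations = 5000L, seed = NULL,
                              score = c("rt_cost", "error_cost"),
                              average = c("corrected", "raw")) {
  n_permutations <- as.integer(n_permutations)
  if (is.na(n_permutations) || n_permutations < 1L)
    stop("n_permutations must be >= 1", call. = FALSE)
  structure(list(n_permutations = n_permutations,
                 seed = if (is.null(seed)) NULL else as.integer(seed),
                 score = match.arg(score),
                 average = match.arg(average)),
            class = "split_half_config")
}

new_reliability_estimate <- function(point, ci_low, ci_high, method,
                                     n_participants, ...) {
  structure(c(list(point = point, ci_low = ci_low, ci_high = ci_high,
                   method = method, n_participants = n_participants),
              list(...)),
            class = "reliability_estimate")
}

#' @export
print.reliability_estimate <- function(x, ...) {
  cat(sprintf("%s: %.3f, 95%% CI %.3f-%.3f (n=%d%s)\n",
              x$method, x$point, x$ci_low, x$ci_high, x$n_participants,
              if (!is.null(x$B)) sprintf(", B=%d", x$B)
              else if (!is.null(x$df)) sprintf(", df=%d", x$df) else ""))
  invisible(x)
}

#' Permutation-based split-half internal consistency
#'
#' For each of B permutations, each participant's trials are randomly
#' partitioned, within each of the congruent and incongruent conditions,
#' into two halves (odd counts: the extra trial goes to a random half).
#' The interference cost is computed on each half, the half costs are
#' Pearson-correlated across participants, and the correlation is
#' Spearman-Brown corrected. The point estimate is the mean of the B
#' corrected values; the 95% CI is their 2.5th/97.5th percentile.
#' Deterministic given `cfg$seed`.
#'
#' For `score = "rt_cost"` the per-trial values are correct-trial RTs;
#' for `score = "error_cost"` they are 0/100 error indicators over all
#' kept trials, so each half's score is an error percentage and halves of
#' unequal size stay comparable.
#'
#' @param trials Kept trials of a single session (one arm).
#' @param cfg A [split_half_config()].
#' @return A `reliability_estimate` (method "splithalf_sb") with the
#'   SB-corrected `point` and percentile CI, plus `raw_mean` (mean
#'   uncorrected split correlation), `B`, and the analyzed participant
#'   count.
#' @export
permutation_split_half <- function(trials, cfg = split_half_config()) {
  stopifnot(inherits(cfg, "split_half_config"))
  tr <- data.table::as.data.table(trials)
  if (data.table::uniqueN(tr$session) > 1L)
    stop("trials must come from a single session", call. = FALSE)

  if (cfg$score == "rt_cost") {
    tr <- tr[correct == 1L & trial_type %in% c("congruent", "incongruent")]
    tr[, value := rt_ms]
  } else {
    tr <- tr[trial_type %in% c("congruent", "incongruent")]
    tr[, value := 100 * (correct == 0L)]
  }

  counts <- tr[, list(n = .N), by = c("participant_id", "trial_type")]
  wide <- data.table::dcast(counts, participant_id ~ trial_type,
                            value.var = "n", fill = 0L)
  for (cn in c("congruent", "incongruent"))
    if (!cn %in% names(wide)) wide[[cn]] <- 0L
  ok_ids <- wide[congruent >= 2L & incongruent >= 2L]$participant_id
  n_dropped <- nrow(wide) - length(ok_ids)
  if (n_dropped > 0L)
    warning(sprintf("%d participant(s) dropped (< 2 trials in a needed condition)",
                    n_dropped), call. = FALSE)
  if (length(ok_ids) < 3L)
    stop("need at least 3 analyzable participants", call. = FALSE)

  tr <- tr[participant_id %in% ok_ids]
  tr[, trial_type := factor(trial_type, levels = c("congruent", "incongruent"))]
  # canonical ordering so results do not depend on input row order
  data.table::setorderv(tr, c("participant_id", "trial_type", "trial_index"))
  blocks <- tr[, list(n = .N), by = c("participant_id", "trial_type")]
  offsets <- c(0L, cumsum(blocks$n))

  if (!is.null(cfg$seed)) set.seed(cfg$seed)
  rs <- split_half_perm_engine(tr$value, as.integer(offsets),
                               length(ok_ids), cfg$n_permutations)
  n_bad <- sum(is.na(rs))
  if (n_bad > 0L)
    warning(sprintf("%d split(s) with degenerate (zero-variance) halves dropped",
                    n_bad), call. = FALSE)
  rs <- rs[!is.na(rs) & rs > -1]
  rs <- pmin(pmax(rs, -1 + 1e-15), 1)  # guard against FP excursions past +/-1
  corrected <- spearman_brown(rs)
  if (cfg$average == "corrected") {
    point <- mean(corrected)
  } else {
    point <- spearman_brown(mean(rs))
  }
  ci <- unname(stats::quantile(corrected, c(0.025, 0.975), type = 7))
  new_reliability_estimate(point, ci[1], ci[2], "splithalf_sb",
                           length(ok_ids), B = cfg$n_permutations,
                           raw_mean = mean(rs), score = cfg$score)
}

#' Compare two independent correlations via Fisher z
#'
#' `z = (atanh r1 - atanh r2) / sqrt(1/(n1-3) + 1/(n2-3))`, with a
#' two-sided p-value from the standard normal.
#'
#' @param r1,r2 Correlations with |r| < 1.
#' @param n1,n2 Sample sizes (> 3).
#' @return A list with `z` and `p`.
#' @export
compare_correlations_fisher <- function(r1, n1, r2, n2) {
  if (n1 <= 3 || n2 <= 3) stop("both n must exceed 3", call. = FALSE)
  if (abs(r1) >= 1 || abs(r2) >= 1) stop("|r| must be < 1", call. = FALSE)
  z <- (atanh(r1) - atanh(r2)) / sqrt(1 / (n1 - 3) + 1 / (n2 - 3))
  list(z = z, p = 2 * stats::pnorm(-abs(z)))
}

#' Pearson test-retest reliability
#'
#' Pearson correlation of a per-participant score across two sessions,
#' with `t = r sqrt(n-2) / sqrt(1-r^2)` on n-2 degrees of freedom and a
#' 95% CI via the Fisher z transform (`atanh(r) +/- 1.96/sqrt(n-3)`).
#' When r = +/-1 the Fisher CI is degenerate and collapses to the point.
#'
#' @param x1,x2 Paired scores at session 1 and session 2.
#' @param conf Confidence level (default 0.95).
#' @return A `reliability_estimate` (method "pearson") with `t` and `df`.
#' @export
test_retest_pearson <- function(x1, x2, conf = 0.95) {
  ok <- stats::complete.cases(x1, x2)
  x1 <- x1[ok]; x2 <- x2[ok]
  n <- length(x1)
  if (n < 4L) stop("need at least 4 paired observations", call. = FALSE)
  if (stats::sd(x1) == 0 || stats::sd(x2) == 0)
    stop("zero variance in a session", call. = FALSE)
  r <- stats::cor(x1, x2)
  if (abs(r) < 1) {
    tstat <- r * sqrt(n - 2) / sqrt(1 - r^2)
    zcrit <- stats::qnorm(1 - (1 - conf) / 2)
    ci <- tanh(atanh(r) + c(-1, 1) * zcrit / sqrt(n - 3))
  } else {
    tstat <- Inf * sign(r)
    ci <- c(r, r)
  }
  new_reliability_estimate(r, ci[1], ci[2], "pearson", n,
                           t = tstat, df = n - 2L,
                           p_value = 2 * stats::pt(-abs(tstat), n - 2))
}

#' Intraclass correlation (Shrout-Fleiss single-rater, two-way)
#'
#' Two-way mean-squares decomposition of an n x k participants-by-sessions
#' matrix: MSR (between participants), MSC (between sessions), MSE
#' (residual). Consistency ICC(3,1) = (MSR - MSE) / (MSR + (k-1) MSE);
#' absolute agreement ICC(2,1) = (MSR - MSE) / (MSR + (k-1) MSE +
#' k (MSC - MSE) / n). Confidence intervals follow the Shrout-Fleiss
#' F-based construction (Satterthwaite degrees of freedom for ICC(2,1)).
#'
#' @param mat Complete numeric matrix, participants in rows, sessions in
#'   columns (n >= 3, k >= 2; no missing values — no imputation).
#' @param type "icc31" (consistency, default) or "icc21" (agreement).
#' @param conf Confidence level (default 0.95).
#' @return An `icc_result`: `icc`, `type`, `msr`, `msc`, `mse`, `F`,
#'   `ci_low`, `ci_high`, `n`, `k`.
#' @export
icc <- function(mat, type = c("icc31", "icc21"), conf = 0.95) {
  type <- match.arg(type)
  mat <- as.matrix(mat)
  n <- nrow(mat); k <- ncol(mat)
  if (n < 3L || k < 2L) stop("need n >= 3 rows and k >= 2 columns", call. = FALSE)
  if (anyNA(mat)) stop("matrix must be complete (no imputation)", call. = FALSE)

  row_means <- rowMeans(mat)
  col_means <- colMeans(mat)
  grand <- mean(mat)
  ssr <- k * sum((row_means - grand)^2)
  ssc <- n * sum((col_means - grand)^2)
  sst <- sum((mat - grand)^2)
  sse <- sst - ssr - ssc
  msr <- ssr / (n - 1)
  msc <- ssc / (k - 1)
  mse <- sse / ((n - 1) * (k - 1))

  alpha <- 1 - conf
  if (type == "icc31") {
    val <- if (msr + (k - 1) * mse == 0) NaN
           else (msr - mse) / (msr + (k - 1) * mse)
    Fstat <- if (mse > 0) msr / mse else Inf
    if (is.finite(Fstat)) {
      fl <- Fstat / stats::qf(1 - alpha / 2, n - 1, (n - 1) * (k - 1))
      fu <- Fstat * stats::qf(1 - alpha / 2, (n - 1) * (k - 1), n - 1)
      ci <- c((fl - 1) / (fl + k - 1), (fu - 1) / (fu + k - 1))
    } else ci <- c(val, val)
  } else {
    denom <- msr + (k - 1) * mse + k * (msc - mse) / n
    val <- if (denom == 0) NaN else (msr - mse) / denom
    Fstat <- if (mse > 0) msr / mse else Inf
    if (is.finite(Fstat) && !is.nan(val)) {
      fj <- msc / mse
      # Satterthwaite df for the ICC(2,1) interval (Shrout-Fleiss)
      vn <- (k - 1) * (n - 1) *
        (k * val * fj + n * (1 + (k - 1) * val) - k * val)^2
      vd <- (n - 1) * k^2 * val^2 * fj^2 +
        (n * (1 + (k - 1) * val) - k * val)^2
      v <- vn / vd
      fl <- stats::qf(1 - alpha / 2, n - 1, v)
      fu <- stats::qf(1 - alpha / 2, v, n - 1)
      lower <- n * (msr - fl * mse) /
        (fl * (k * msc + (k * n - k - n) * mse) + n * msr)
      upper <- n * (fu * msr - mse) /
        (k * msc + (k * n - k - n) * mse + n * fu * msr)
      ci <- c(lower, upper)
    } else ci <- c(val, val)
  }
  structure(list(icc = val, type = type, msr = msr, msc = msc, mse = mse,
                 F = Fstat, ci_low = ci[1], ci_high = ci[2], n = n, k = k),
            class = "icc_result")
}

#' @export
print.icc_result <- function(x, ...) {
  lab <- if (x$type == "icc31") "ICC(3,1) consistency" else "ICC(2,1) agreement"
  cat(sprintf("%s: %.3f, 95%% CI %.3f-%.3f (n=%d, k=%d)\n",
              lab, x$icc, x$ci_low, x$ci_high, x$n, x$k))
  invisible(x)
}

# Per-participant-session metric from the first t kept trials per
# condition (presentation order). Returns pid, session, value.
first_t_metric <- function(prep, t, score, per_type = FALSE) {
  at_t <- prep[, {
    j <- min(t, .N)
    if (score == "rt_cost") {
      nc <- cs_n_corr[j]
      list(value = if (nc > 0) cs_rt_corr[j] / nc else NA_real_)
    } else {
      list(value = 100 * (1 - cs_n_corr[j] / j))
    }
  }, by = c("participant_id", "session", "trial_type")]
  if (per_type) return(at_t)
  wide <- data.table::dcast(at_t[trial_type %in% c("congruent", "incongruent")],
                            participant_id + session ~ trial_type,
                            value.var = "value")
  wide[, list(participant_id, session, value = incongruent - congruent)]
}

#' Reliability as a function of trial count
#'
#' Recomputes the score from only the first t kept trials per condition
#' (presentation order) in each session, for t on a grid, and estimates
#' its test-retest reliability across the two sessions at each t — the
#' standard way to ask how many trials a stable interference estimate
#' needs. Participants with fewer than t kept trials in a condition
#' contribute all their kept trials (keeping n constant across the grid);
#' the affected count is returned per grid point.
#'
#' @param cohort A screened two-session `stroop_cohort` (or trial table),
#'   typically a single arm.
#' @param metric "cost" (interference cost per session) or "per_type"
#'   (per-trial-type mean RT or error percentage, one curve per type).
#' @param score "rt_cost" / "error_cost" flavor of the metric.
#' @param step Grid step in trials per condition (default 10).
#' @param estimator "icc31" (default) or "pearson".
#' @return A `reliability_curve`: data.table with columns `metric`,
#'   `trial_type` (`NA` for the cost metric), `t`, `estimate`,
#'   `n_participants`, `n_capped` (participants contributing fewer than t
#'   trials in some condition).
#' @export
reliability_curve <- function(cohort, metric = c("cost", "per_type"),
                              score = c("rt_cost", "error_cost"),
                              step = 10L,
                              estimator = c("icc31", "pearson")) {
  metric <- match.arg(metric)
  score <- match.arg(score)
  estimator <- match.arg(estimator)
  tr <- if (inherits(cohort, "stroop_cohort")) cohort$trials
        else data.table::as.data.table(cohort)
  plan <- if (inherits(cohort, "stroop_cohort")) cohort$plan else session_plan()
  sessions <- sort(unique(tr$session))
  if (length(sessions) != 2L)
    stop("reliability_curve needs exactly two sessions", call. = FALSE)

  data.table::setorderv(tr, c("participant_id", "session", "trial_index"))
  prep <- tr[, list(cs_rt_corr = cumsum(rt_ms * (correct == 1L)),
                    cs_n_corr = cumsum(correct == 1L)),
             by = c("participant_id", "session", "trial_type")]

  max_n <- tr[, list(n = .N),
              by = c("participant_id", "session", "trial_type")]
  grid <- unique(c(seq(step, plan$n_per_condition, by = step),
                   plan$n_per_condition))

  est_fun <- function(wide_mat) {
    if (estimator == "icc31") icc(wide_mat, "icc31")$icc
    else stats::cor(wide_mat[, 1], wide_mat[, 2])
  }

  rows <- list()
  for (t in grid) {
    vals <- first_t_metric(prep, t, score, per_type = (metric == "per_type"))
    types <- if (metric == "per_type") TRIAL_TYPES else NA_character_
    relevant <- if (metric == "per_type") max_n
                else max_n[trial_type %in% c("congruent", "incongruent")]
    n_capped <- data.table::uniqueN(relevant[n < t]$participant_id)
    for (tt in types) {
      v <- if (metric == "per_type") vals[trial_type == tt] else vals
      wide <- data.table::dcast(v, participant_id ~ session,
                                value.var = "value")
      wide <- wide[stats::complete.cases(wide)]
      if (nrow(wide) < 3L) next
      m <- as.matrix(wide[, -1])
      rows[[length(rows) + 1L]] <- data.table::data.table(
        metric = metric, trial_type = tt, t = t,
        estimate = est_fun(m), n_participants = nrow(wide),
        n_capped = n_capped)
    }
  }
  out <- data.table::rbindlist(rows)
  data.table::setattr(out, "class", c("reliability_curve", class(out)))
  out[]
}
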