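# Hierarchical two-session, two-arm Stroop cohort simulator with known
# ground-truth reliability, plus the gamified points-scoring rules and
# closed-form reliability oracles.

#' Parameters of the synthetic Stroop cohort generator
#'
#' Defines the hierarchical reaction-time model underlying
#' [generate_cohort()]. For subject i and session s, condition means are
#'
#'   m = mu_congruent + a_is + delta_neutral * 1(neutral)
#'       + (beta_stroop + u_is) * 1(incongruent)
#'       - game_speed_shift_t1 * 1(game arm, s = 1)
#'
#' where the subject baselines (a_i1, a_i2) are bivariate normal with SD
#' `sigma_subject` and cross-session correlation `rho_baseline`, and the
#' subject interference effects (u_i1, u_i2) are bivariate normal with SD
#' `sigma_effect` and correlation `rho_effect`. Single-trial RTs are
#' lognormal, moment-matched to (m, `sigma_trial`); with probability
#' `lapse_prob` (per arm) a trial is replaced by an attention-lapse
#' contaminant drawn uniformly on `lapse_range`. Response correctness is
#' Bernoulli with a per-condition error rate, independent of RT.
#'
#' Defaults are calibrated to a published two-arm gamified Stroop study:
#' congruent means around 638-678 ms, a population interference cost near
#' 110-118 ms with subject SD ~ 45 ms, incongruent error rates about twice
#' the congruent rate, a game-arm speed-up of ~30 ms at session 1 only, and
#' about half as many lapse trials in the game arm.
#'
#' @param n_per_arm Participants per arm.
#' @param arms Character vector of arms to simulate ("basic", "game").
#' @param plan A [session_plan()].
#' @param mu_congruent Population congruent mean RT, ms.
#' @param delta_neutral Neutral-minus-congruent shift, ms.
#' @param beta_stroop Population incongruent-minus-congruent effect, ms.
#' @param sigma_subject SD of the subject baseline a_i, ms.
#' @param sigma_effect SD of the subject Stroop effect u_i, ms.
#' @param rho_baseline,rho_effect Cross-session correlations of a_i and of
#'   the per-session effect b_is = beta_stroop + u_is, in \[-1, 1\].
#' @param sigma_trial Within-subject single-trial SD, ms.
#' @param lapse_prob Probability of a contaminant slow trial; named vector
#'   `c(basic = ..., game = ...)` or a single value used for both arms.
#' @param lapse_range Two-vector (low, high), ms, for contaminant RTs.
#' @param error_rates Named per-condition error probabilities.
#' @param game_speed_shift_t1 Milliseconds subtracted from game-arm
#'   condition means at session 1 only.
#' @param trial_dist "lognormal" (default; right-skewed, positive) or
#'   "normal" (for closed-form checks; values clamped to be positive).
#' @param seed Integer RNG seed, or `NULL` to use the current RNG state.
#' @return An object of class `generator_params`.
#' @seealso [generate_cohort()], [analytic_split_half_r()],
#'   [analytic_retest_icc()]
#' @export
generator_params <- function(n_per_arm = 50L,
                             arms = c("basic", "game"),
                             plan = session_plan(),
                             mu_congruent = 660,
                             delta_neutral = -8,
                             beta_stroop = 110,
                             sigma_subject = 90,
                             sigma_effect = 45,
                             rho_baseline = 0.8,
                             rho_effect = 0.7,
                             sigma_trial = 150,
                             lapse_prob = c(basic = 0.03, game = 0.015),
                             lapse_range = c(1400, 2600),
                             error_rates = c(congruent = 0.045,
                                             neutral = 0.035,
                                             incongruent = 0.07),
                             game_speed_shift_t1 = 30,
                             trial_dist = c("lognormal", "normal"),
                             seed = NULL) {
  trial_dist <- match.arg(trial_dist)
  arms <- match.arg(arms, ARMS, several.ok = TRUE)
  if (length(lapse_prob) == 1L && is.null(names(lapse_prob)))
    lapse_prob <- c(basic = unname(lapse_prob), game = unname(lapse_prob))
  p <- structure(
    list(n_per_arm = as.integer(n_per_arm), arms = arms, plan = plan,
         mu_congruent = mu_congruent, delta_neutral = delta_neutral,
         beta_stroop = beta_stroop, sigma_subject = sigma_subject,
         sigma_effect = sigma_effect, rho_baseline = rho_baseline,
         rho_effect = rho_effect, sigma_trial = sigma_trial,
         lapse_prob = lapse_prob, lapse_range = lapse_range,
         error_rates = error_rates,
         game_speed_shift_t1 = game_speed_shift_t1,
         trial_dist = trial_dist,
         seed = if (is.null(seed)) NULL else as.integer(seed)),
    class = "generator_params")
  validate_generator_params(p)
  p
}

validate_generator_params <- function(p) {
  if (p$n_per_arm < 1L) stop("n_per_arm must be >= 1", call. = FALSE)
  if (any(c(p$sigma_subject, p$sigma_effect, p$sigma_trial) < 0))
    stop("all SDs must be >= 0", call. = FALSE)
  if (any(abs(c(p$rho_baseline, p$rho_effect)) > 1))
    stop("correlations must lie in [-1, 1]", call. = FALSE)
  if (any(p$lapse_prob < 0 | p$lapse_prob > 1) ||
      any(p$error_rates < 0 | p$error_rates > 1))
    stop("probabilities must lie in [0, 1]", call. = FALSE)
  if (length(p$lapse_range) != 2L || p$lapse_range[1] <= 0 ||
      p$lapse_range[2] <= p$lapse_range[1])
    stop("lapse_range must satisfy 0 < low < high", call. = FALSE)
  if (!all(names(p$error_rates) %in% TRIAL_TYPES) ||
      !all(TRIAL_TYPES %in% names(p$error_rates)))
    stop("error_rates must be named for all three trial types", call. = FALSE)
  invisible(p)
}

#' Gamified points-scoring rules
#'
#' The game arm awards +5 points for a correct answer, -5 for an incorrect
#' answer, and a +25 bonus for correct responses that break the
#' participant's running "fastest time" record.
#'
#' @param gain_correct,loss_incorrect,bonus_record Point values.
#' @return An object of class `points_rules`.
#' @export
points_rules <- function(gain_correct = 5L, loss_incorrect = -5L,
                         bonus_record = 25L) {
  structure(list(gain_correct = as.integer(gain_correct),
                 loss_incorrect = as.integer(loss_incorrect),
                 bonus_record = as.integer(bonus_record)),
            class = "points_rules")
}

# Bivariate normal pairs (x1, x2), marginal SD `sd`, correlation `rho`.
rbvn_pair <- function(n, sd, rho) {
  z1 <- stats::rnorm(n)
  z2 <- stats::rnorm(n)
  cbind(sd * z1, sd * (rho * z1 + sqrt(1 - rho^2) * z2))
}

# Lognormal draws moment-matched to mean m (vector) and SD s.
rlnorm_matched <- function(m, s) {
  if (s == 0) return(m)
  sdlog2 <- log1p((s / m)^2)
  stats::rlnorm(length(m), meanlog = log(m) - sdlog2 / 2,
                sdlog = sqrt(sdlog2))
}

#' Generate a synthetic two-session Stroop cohort
#'
#' Simulates trial-level data under the hierarchical model described in
#' [generator_params()]. The output is a valid `stroop_cohort` carrying
#' `participant_id`, `session`, `arm`, 0-based `trial_index` (trial types
#' randomly interleaved within each session), `trial_type`, `correct`, and
#' `rt_ms` (rounded to 3 decimals, the CSV serialization precision).
#' Deterministic given `params$seed`.
#'
#' @param params A [generator_params()] object.
#' @return A `stroop_cohort`.
#' @examples
#' cohort <- generate_cohort(generator_params(n_per_arm = 4, seed = 1))
#' cohort
#' @export
generate_cohort <- function(params) {
  stopifnot(inherits(params, "generator_params"))
  validate_generator_params(params)
  if (!is.null(params$seed)) set.seed(params$seed)

  plan <- params$plan
  npc <- plan$n_per_condition
  n_sess <- plan$n_sessions
  types <- rep(TRIAL_TYPES, each = npc)
  n_trials <- length(types)

  arm_prefix <- c(basic = "b", game = "g")
  pieces <- vector("list", 0L)

  for (arm in params$arms) {
    ids <- sprintf("%s%03d", arm_prefix[[arm]], seq_len(params$n_per_arm))
    a <- rbvn_pair(params$n_per_arm, params$sigma_subject, params$rho_baseline)
    u <- rbvn_pair(params$n_per_arm, params$sigma_effect, params$rho_effect)
    if (n_sess > 2L)
      stop("generator supports at most 2 sessions", call. = FALSE)
    lp <- unname(params$lapse_prob[[arm]])

    for (i in seq_len(params$n_per_arm)) {
      for (s in seq_len(n_sess)) {
        m <- params$mu_congruent + a[i, s] +
          params$delta_neutral * (types == "neutral") +
          (params$beta_stroop + u[i, s]) * (types == "incongruent") -
          params$game_speed_shift_t1 * (arm == "game" && s == 1L)
        if (any(m <= 0))
          stop("parameters imply a non-positive condition mean RT",
               call. = FALSE)
        ord <- sample.int(n_trials)
        m_ord <- m[ord]
        if (params$trial_dist == "lognormal") {
          rt <- rlnorm_matched(m_ord, params$sigma_trial)
        } else {
          rt <- pmax(stats::rnorm(n_trials, m_ord, params$sigma_trial), 1)
        }
        if (lp > 0) {
          is_lapse <- stats::runif(n_trials) < lp
          rt[is_lapse] <- stats::runif(sum(is_lapse),
                                       params$lapse_range[1],
                                       params$lapse_range[2])
        }
        correct <- stats::rbinom(n_trials, 1L,
                                 1 - unname(params$error_rates[types[ord]]))
        pieces[[length(pieces) + 1L]] <- data.table::data.table(
          participant_id = ids[i], session = s, arm = arm,
          trial_index = seq_len(n_trials) - 1L,
          trial_type = types[ord], correct = correct,
          rt_ms = round(rt, 3))
      }
    }
  }
  as_cohort(data.table::rbindlist(pieces), plan = plan)
}

#' Score one session under the gamified points rules
#'
#' Replays a session in presentation order and applies the points rules:
#' each correct response earns `gain_correct`; the first correct response
#' initializes the running fastest-time record without a bonus; later
#' correct responses whose RT strictly beats the record earn
#' `bonus_record` on top (and update the record); incorrect responses earn
#' `loss_incorrect` and never touch the record.
#'
#' @param trials A data.frame of one participant-session's trials with
#'   columns `trial_index`, `correct`, `rt_ms`.
#' @param rules A [points_rules()] object.
#' @return A list: `total` score and `deltas`, the per-trial point changes
#'   in presentation order.
#' @examples
#' tr <- data.frame(trial_index = 0:2, correct = 1,
#'                  rt_ms = c(600, 550, 580))
#' score_points(tr, points_rules())$total  # 5 + (5 + 25) + 5 = 45
#' @export
score_points <- function(trials, rules = points_rules()) {
  stopifnot(inherits(rules, "points_rules"))
  if (NROW(trials) == 0L) return(list(total = 0L, deltas = integer(0)))
  trials <- as.data.frame(trials)[order(trials$trial_index), , drop = FALSE]
  correct <- as.logical(trials$correct)
  rt <- trials$rt_ms
  deltas <- integer(nrow(trials))
  record <- Inf
  seen_correct <- FALSE
  for (j in seq_along(deltas)) {
    if (!correct[j]) {
      deltas[j] <- rules$loss_incorrect
      next
    }
    deltas[j] <- rules$gain_correct
    if (!seen_correct) {
      record <- rt[j]
      seen_correct <- TRUE
    } else if (rt[j] < record) {
      deltas[j] <- deltas[j] + rules$bonus_record
      record <- rt[j]
    }
  }
  list(total = sum(deltas), deltas = deltas)
}

#' Expected half-half correlation of the interference cost
#'
#' Closed-form oracle for the permutation split-half procedure under the
#' generator's model without contaminants. With `m` trials per condition
#' per half, the cost computed on a half has true-score variance
#' `sigma_effect^2` and noise variance `2 * sigma_trial^2 / m`, so the
#' expected correlation between the two half costs within one session is
#'
#'   sigma_effect^2 / (sigma_effect^2 + 2 * sigma_trial^2 / m)
#'
#' @param params A [generator_params()] with `lapse_prob = 0` (the closed
#'   form assumes no contaminant trials; a warning is issued otherwise).
#' @param m Trials per condition per half.
#' @return Expected uncorrected half-half Pearson correlation.
#' @seealso [spearman_brown()] to project to full length;
#'   [analytic_retest_icc()]
#' @export
analytic_split_half_r <- function(params, m) {
  stopifnot(inherits(params, "generator_params"))
  if (m <= 0) stop("m must be positive", call. = FALSE)
  if (any(params$lapse_prob > 0))
    warning("closed form assumes lapse_prob = 0", call. = FALSE)
  v_true <- params$sigma_effect^2
  v_noise <- 2 * params$sigma_trial^2 / m
  if (v_true + v_noise == 0) return(NaN)
  v_true / (v_true + v_noise)
}

#' Expected test-retest ICC(3,1) of the interference cost
#'
#' Closed-form oracle for two-session cost consistency under the
#' generator's model without contaminants: the cross-session correlation
#' of the per-session effect, attenuated by trial-sampling noise with `n`
#' trials per condition:
#'
#'   rho_effect * sigma_effect^2 / (sigma_effect^2 + 2 * sigma_trial^2 / n)
#'
#' As `n` grows the value approaches `rho_effect`.
#'
#' @param params A [generator_params()] with `lapse_prob = 0`.
#' @param n Trials per condition contributing to each session's cost.
#' @return Expected ICC(3,1) between session-1 and session-2 costs.
#' @export
analytic_retest_icc <- function(params, n) {
  stopifnot(inherits(params, "generator_params"))
  if (n <= 0) stop("n must be positive", call. = FALSE)
  if (any(params$lapse_prob > 0))
    warning("closed form assumes lapse_prob = 0", call. = FALSE)
  v_true <- params$sigma_effect^2
  v_noise <- 2 * params$sigma_trial^2 / n
  if (v_true + v_noise == 0) return(NaN)
  params$rho_effect * v_true / (v_true + v_noise)
}
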