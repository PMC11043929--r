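# Fixture builders shared across the suite. All fixtures are constructed
# in code; nothing is read from disk.

# Bare trial table. `rt` is recycled across trials; one participant-session.
make_trials <- function(pid = "p1", session = 1L, arm = "basic",
                        trial_type = "congruent", correct = 1L, rt = 500) {
  n <- max(length(rt), length(trial_type), length(correct))
  data.frame(
    participant_id = pid, session = session, arm = arm,
    trial_index = seq_len(n) - 1L,
    trial_type = rep_len(trial_type, n),
    correct = rep_len(correct, n),
    rt_ms = rep_len(rt, n))
}

# Small deterministic cohort: n participants x 2 sessions, `npc` trials per
# condition, RTs drawn around per-participant means. Valid stroop_cohort.
tiny_cohort <- function(n = 6L, npc = 12L, arm = "basic", seed = 99L,
                        sessions = 1:2) {
  set.seed(seed)
  rows <- list()
  for (i in seq_len(n)) {
    base <- 500 + i * 20
    eff <- 80 + i * 10
    for (s in sessions) {
      types <- rep(c("congruent", "neutral", "incongruent"), each = npc)
      m <- base + ifelse(types == "incongruent", eff, 0)
      rows[[length(rows) + 1L]] <- data.frame(
        participant_id = sprintf("%s%02d", substr(arm, 1, 1), i),
        session = s, arm = arm,
        trial_index = seq_along(types) - 1L,
        trial_type = types,
        correct = rbinom(length(types), 1, 0.95),
        rt_ms = round(pmax(100, rnorm(length(types), m, 40)), 3))
    }
  }
  as_cohort(do.call(rbind, rows),
            plan = session_plan(n_per_condition = npc,
                                n_sessions = length(sessions)))
}

# Independent two-way mean-squares ICC oracle built on stats::aov().
icc_oracle <- function(mat, type) {
  n <- nrow(mat); k <- ncol(mat)
  d <- data.frame(y = as.vector(mat),
                  row = factor(rep(seq_len(n), times = k)),
                  col = factor(rep(seq_len(k), each = n)))
  ms <- summary(stats::aov(y ~ row + col, data = d))[[1]][["Mean Sq"]]
  msr <- ms[1]; msc <- ms[2]; mse <- ms[3]
  if (type == "icc31") (msr - mse) / (msr + (k - 1) * mse)
  else (msr - mse) / (msr + (k - 1) * mse + k * (msc - mse) / n)
}
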