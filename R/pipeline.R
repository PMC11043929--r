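# End-to-end orchestration: simulate (or load) -> screen -> summarize ->
# reliability, with a machine-readable JSON report and CSV artifacts.

PIPELINE_REPORT_VERSION <- "1"

default_run_config <- function() {
  list(
    generator = NULL,          # list of generator_params() overrides
    input = NULL,              # or: path to a trial CSV
    screening = list(),        # screening_config() overrides
    split_half = list(n_permutations = 5000L, score = "rt_cost"),
    curve = list(step = 10L, estimator = "icc31", enabled = TRUE),
    out_dir = ".",
    seed = 1L,
    log = TRUE)
}

#' Validate and normalize a pipeline configuration
#'
#' Reads a YAML (`.yaml`/`.yml`) or JSON configuration file, or takes a
#' list, fills in defaults, and rejects unknown or contradictory keys.
#' Exactly one of `generator` (simulation parameters) and `input` (path
#' to a trial CSV) must be supplied.
#'
#' @param config Path to a YAML/JSON file, or a named list.
#' @return A normalized `run_config` list.
#' @export
validate_config <- function(config) {
  if (is.character(config) && length(config) == 1L) {
    if (!file.exists(config)) stop("config file not found: ", config,
                                   call. = FALSE)
    config <- if (grepl("\\.ya?ml$", config, ignore.case = TRUE))
      yaml::read_yaml(config)
    else jsonlite::fromJSON(config, simplifyVector = TRUE)
    if (is.null(config)) config <- list()
  }
  if (!is.list(config)) stop("config must be a file path or a list",
                             call. = FALSE)
  defaults <- default_run_config()
  unknown <- setdiff(names(config), names(defaults))
  if (length(unknown) > 0L)
    stop("unknown config key(s): ", paste(unknown, collapse = ", "),
         call. = FALSE)
  cfg <- utils::modifyList(defaults, config)

  errors <- character(0)
  if (!is.null(cfg$generator) && !is.null(cfg$input))
    errors <- c(errors, "supply exactly one of 'generator' and 'input', not both")
  if (is.null(cfg$generator) && is.null(cfg$input))
    errors <- c(errors, "one of 'generator' or 'input' is required")
  if (!is.null(cfg$split_half$n_permutations) &&
      cfg$split_half$n_permutations < 1)
    errors <- c(errors, "split_half.n_permutations must be >= 1")
  if (!is.numeric(cfg$seed) || length(cfg$seed) != 1L || cfg$seed < 0 ||
      cfg$seed != floor(cfg$seed))
    errors <- c(errors, "seed must be a non-negative integer")
  if (!is.null(cfg$curve$step) && cfg$curve$step < 1)
    errors <- c(errors, "curve.step must be >= 1")
  if (length(errors) > 0L)
    stop("invalid config:\n  - ", paste(errors, collapse = "\n  - "),
         call. = FALSE)
  cfg$seed <- as.integer(cfg$seed)
  structure(cfg, class = "run_config")
}

plog <- function(enabled, fmt, ...) {
  if (enabled) message(sprintf(fmt, ...))
  invisible(NULL)
}

# Stage seeds derived from the global seed by fixed offsets so each stage
# is independently reproducible. Kept below 2^31.
stage_seed <- function(seed, stage) {
  (as.integer(seed) + c(simulate = 1L, splithalf = 2L, curve = 3L)[[stage]]) %%
    .Machine$integer.max
}

#' Run the full analysis pipeline
#'
#' Executes simulate/load -> screening -> descriptive cost table ->
#' split-half internal consistency per (arm, session) -> test-retest
#' (Pearson, ICC(2,1), ICC(3,1)) per arm -> reliability curves per arm,
#' and writes `kept.csv`, `report.json` and `curves.csv` into
#' `config$out_dir`. Identical config and seed give an identical report.
#'
#' @param config A `run_config` (see [validate_config()]), a list, or a
#'   path to a YAML/JSON config file.
#' @return An `analysis_report` list (invisibly written to
#'   `report.json`): screening ledger, summary table, reliability
#'   estimates with CIs and n, curves, version and config echo.
#' @export
run_pipeline <- function(config) {
  cfg <- if (inherits(config, "run_config")) config else validate_config(config)
  dir.create(cfg$out_dir, showWarnings = FALSE, recursive = TRUE)
  log <- isTRUE(cfg$log)

  # stage 1: obtain cohort
  if (!is.null(cfg$generator)) {
    gp_args <- cfg$generator
    if (!is.null(gp_args$plan) && !inherits(gp_args$plan, "session_plan"))
      gp_args$plan <- do.call(session_plan, gp_args$plan)
    if (is.null(gp_args$seed)) gp_args$seed <- stage_seed(cfg$seed, "simulate")
    params <- do.call(generator_params, gp_args)
    cohort <- generate_cohort(params)
    plog(log, "simulate: %d participants, %d trials",
         data.table::uniqueN(cohort$trials$participant_id),
         nrow(cohort$trials))
  } else {
    cohort <- read_trials(cfg$input)
    plog(log, "load: %s (%d trials)", cfg$input, nrow(cohort$trials))
  }

  # stage 2: screening
  scr_cfg <- do.call(screening_config, cfg$screening)
  scr <- apply_screening(cohort, scr_cfg)
  kept <- scr$cohort
  plog(log, "screen: %d/%d trials kept, %d participants excluded",
       scr$report$n_trials_kept, scr$report$n_trials_input,
       length(scr$report$excluded_participant_ids))

  # stage 3: descriptive summaries
  summary_table <- cohort_cost_table(kept)

  # stage 4: split-half per (arm, session, score)
  tr <- kept$trials
  sh_results <- list()
  for (arm_i in sort(unique(tr$arm))) {
    for (sess in sort(unique(tr$session))) {
      for (sc in c("rt_cost", "error_cost")) {
        sh_cfg <- split_half_config(
          n_permutations = cfg$split_half$n_permutations,
          seed = stage_seed(cfg$seed, "splithalf"),
          score = sc)
        est <- permutation_split_half(tr[arm == arm_i & session == sess],
                                      sh_cfg)
        sh_results[[sprintf("%s.session%d.%s", arm_i, sess, sc)]] <-
          unclass(est)
      }
    }
  }
  plog(log, "split-half: %d estimates (B=%d)", length(sh_results),
       cfg$split_half$n_permutations)

  # stage 5: test-retest per (arm, score)
  costs <- participant_costs(tr)
  tt_results <- list()
  if (data.table::uniqueN(tr$session) == 2L) {
    for (arm_i in sort(unique(costs$arm))) {
      for (sc in c("rt_cost", "error_cost")) {
        wide <- data.table::dcast(costs[arm == arm_i],
                                  participant_id ~ session,
                                  value.var = sc)
        wide <- wide[stats::complete.cases(wide)]
        m <- as.matrix(wide[, -1])
        if (nrow(m) < 4L) next
        tt_results[[sprintf("%s.%s", arm_i, sc)]] <- list(
          pearson = unclass(test_retest_pearson(m[, 1], m[, 2])),
          icc21 = unclass(icc(m, "icc21")),
          icc31 = unclass(icc(m, "icc31")))
      }
    }
    plog(log, "test-retest: %d arm x score cells", length(tt_results))
  }

  # stage 6: reliability curves per arm
  curves <- data.table::data.table()
  if (isTRUE(cfg$curve$enabled) && data.table::uniqueN(tr$session) == 2L) {
    curve_list <- list()
    for (arm_i in sort(unique(tr$arm))) {
      for (sc in c("rt_cost", "error_cost")) {
        cv <- reliability_curve(tr[arm == arm_i], metric = "cost",
                                score = sc, step = cfg$curve$step,
                                estimator = cfg$curve$estimator)
        cv[, `:=`(arm = arm_i, score = sc)]
        curve_list[[length(curve_list) + 1L]] <- cv
      }
    }
    curves <- data.table::rbindlist(curve_list)
    plog(log, "curves: %d grid points", nrow(curves))
  }

  report <- list(
    version = PIPELINE_REPORT_VERSION,
    config = cfg[setdiff(names(cfg), "log")],
    screening = list(
      n_trials_input = scr$report$n_trials_input,
      n_trials_trimmed = scr$report$n_trials_trimmed,
      n_trials_kept = scr$report$n_trials_kept,
      removed_by_rule = scr$report$removed_trials_total_by_rule,
      incomplete_participants = scr$report$incomplete_participants,
      excluded_participants = scr$report$excluded_participant_ids),
    summary_table = summary_table,
    split_half = sh_results,
    test_retest = tt_results,
    curves = curves)
  class(report) <- "analysis_report"

  write_trials(kept, file.path(cfg$out_dir, "kept.csv"))
  jsonlite::write_json(unclass(report),
                       file.path(cfg$out_dir, "report.json"),
                       auto_unbox = TRUE, digits = NA, null = "null",
                       dataframe = "rows", pretty = TRUE)
  if (nrow(curves) > 0L)
    data.table::fwrite(curves, file.path(cfg$out_dir, "curves.csv"))
  invisible(report)
}

#' Command-line entry point
#'
#' Subcommand dispatcher backing the `strooprel` executable script
#' (`inst/exec/strooprel`): `simulate`, `screen`, `summarize`,
#' `reliability` and `run`. Arguments are `--key value` pairs; see the
#' `usage` output (`strooprel_main(character(0))`).
#'
#' @param args Character vector of command-line arguments (defaults to
#'   `commandArgs(trailingOnly = TRUE)`).
#' @return Exit status, invisibly (0 on success).
#' @export
strooprel_main <- function(args = commandArgs(trailingOnly = TRUE)) {
  usage <- paste(
    "usage: strooprel <command> [--key value ...]",
    "commands:",
    "  simulate    --out cohort.csv [--n-per-arm N] [--seed S]",
    "  screen      --in trials.csv --out kept.csv [--report report.json]",
    "  summarize   --in kept.csv --out table.csv",
    "  reliability --in kept.csv --out reliability.json [--splits B] [--seed S]",
    "              [--score rt_cost|error_cost]",
    "  run         --config cfg.yaml [--out-dir DIR]",
    sep = "\n")
  if (length(args) < 1L) { cat(usage, "\n"); return(invisible(1L)) }
  cmd <- args[1]
  kv <- parse_cli_args(args[-1])
  opt <- function(name, default = NULL) {
    if (name %in% names(kv)) kv[[name]] else default
  }

  switch(cmd,
    simulate = {
      params <- generator_params(
        n_per_arm = as.integer(opt("n-per-arm", 50L)),
        seed = as.integer(opt("seed", 1L)))
      write_trials(generate_cohort(params), opt("out", "cohort.csv"))
    },
    screen = {
      cohort <- read_trials(opt("in"))
      scr <- apply_screening(cohort, screening_config())
      write_trials(scr$cohort, opt("out", "kept.csv"))
      rp <- opt("report")
      if (!is.null(rp))
        jsonlite::write_json(
          list(n_trials_input = scr$report$n_trials_input,
               n_trials_kept = scr$report$n_trials_kept,
               removed_by_rule = scr$report$removed_trials_total_by_rule,
               excluded_participants = scr$report$excluded_participant_ids),
          rp, auto_unbox = TRUE, digits = NA, dataframe = "rows")
      print(scr$report)
    },
    summarize = {
      cohort <- read_trials(opt("in"))
      data.table::fwrite(cohort_cost_table(cohort),
                         opt("out", "table.csv"))
    },
    reliability = {
      cohort <- read_trials(opt("in"))
      tr <- cohort$trials
      out <- list()
      for (arm_i in sort(unique(tr$arm)))
        for (sess in sort(unique(tr$session)))
          out[[sprintf("%s.session%d", arm_i, sess)]] <- unclass(
            permutation_split_half(tr[arm == arm_i & session == sess],
              split_half_config(
                n_permutations = as.integer(opt("splits", 5000L)),
                seed = as.integer(opt("seed", 1L)),
                score = opt("score", "rt_cost"))))
      jsonlite::write_json(out, opt("out", "reliability.json"),
                           auto_unbox = TRUE, digits = NA)
    },
    run = {
      cfg <- validate_config(opt("config"))
      od <- opt("out-dir")
      if (!is.null(od)) cfg$out_dir <- od
      run_pipeline(cfg)
    },
    { cat("unknown command:", cmd, "\n", usage, "\n"); return(invisible(1L)) })
  invisible(0L)
}

parse_cli_args <- function(args) {
  kv <- list()
  i <- 1L
  while (i <= length(args)) {
    if (!startsWith(args[i], "--"))
      stop("unexpected argument: ", args[i], call. = FALSE)
    key <- sub("^--", "", args[i])
    if (i == length(args) || startsWith(args[i + 1L], "--"))
      stop("missing value for --", key, call. = FALSE)
    kv[[key]] <- args[i + 1L]
    i <- i + 2L
  }
  kv
}
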