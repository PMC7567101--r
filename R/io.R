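TRIAL_LOG_COLUMNS <- c("student_id", "item_id", "time_s", "kind", "outcome",
                       "rt_s")

#' Read and write trial-log CSV files
#'
#' The trial-log interchange format is a plain UTF-8 comma-separated file
#' with header \code{student_id,item_id,time_s,kind,outcome,rt_s} ('.'
#' decimal separator).  Extra columns (design assignments) are preserved on
#' write and ignored by consumers that do not need them.
#'
#' @param table a trial table data frame.
#' @param path file path.
#' @return \code{read_trial_log} returns the trial table;
#'   \code{write_trial_log} returns \code{path} invisibly.
#' @export
write_trial_log <- function(table, path) {
  miss <- setdiff(TRIAL_LOG_COLUMNS, names(table))
  if (length(miss) > 0)
    stop("trial table is missing columns: ", paste(miss, collapse = ", "))
  ordered <- table[, c(TRIAL_LOG_COLUMNS,
                       setdiff(names(table), TRIAL_LOG_COLUMNS))]
  utils::write.csv(ordered, path, row.names = FALSE, quote = FALSE,
                   na = "")
  invisible(path)
}

#' @rdname write_trial_log
#' @export
read_trial_log <- function(path) {
  tab <- utils::read.csv(path, stringsAsFactors = FALSE)
  miss <- setdiff(TRIAL_LOG_COLUMNS, names(tab))
  if (length(miss) > 0)
    stop("trial log is missing columns: ", paste(miss, collapse = ", "))
  if (nrow(tab) == 0L) stop("trial log is empty")
  tab
}

# strict config validation: every key must be known
check_keys <- function(config, allowed, where) {
  unknown <- setdiff(names(config), allowed)
  if (length(unknown) > 0)
    stop(sprintf("unknown key(s) in %s: %s", where,
                 paste(unknown, collapse = ", ")))
  invisible(config)
}

#' Read a JSON run configuration
#'
#' Strictly-validated JSON configuration for the command-line pipeline.
#' Recognized blocks: \code{design} ([study_design()] fields),
#' \code{params} ([model_params()] fields), \code{latency}
#' ([latency_params()] fields), \code{timing} ([timing_constants()]
#' fields), \code{schedule} ([schedule_spec()] fields), \code{condition}
#' ([sim_condition()] scalar fields), \code{fit} (options of
#' [fit_correctness()]), \code{thresholds}, \code{n_students},
#' \code{seed}, \code{rt_noise_sd}.  Unknown keys are rejected.
#'
#' @param path path to a JSON file.
#' @return The validated configuration list.
#' @export
read_run_config <- function(path) {
  config <- jsonlite::read_json(path, simplifyVector = TRUE)
  check_keys(config, c("design", "params", "latency", "timing", "schedule",
                       "condition", "fit", "thresholds", "n_students",
                       "seed", "rt_noise_sd"), "config")
  if (!is.null(config$design))
    check_keys(config$design,
               names(formals(study_design)), "config$design")
  if (!is.null(config$params))
    check_keys(config$params, names(formals(model_params)), "config$params")
  if (!is.null(config$latency))
    check_keys(config$latency, names(formals(latency_params)),
               "config$latency")
  if (!is.null(config$timing))
    check_keys(config$timing, names(formals(timing_constants)),
               "config$timing")
  if (!is.null(config$schedule))
    check_keys(config$schedule, names(formals(schedule_spec)),
               "config$schedule")
  if (!is.null(config$condition))
    check_keys(config$condition,
               setdiff(names(formals(sim_condition)), c("schedule", "timing")),
               "config$condition")
  if (!is.null(config$fit))
    check_keys(config$fit,
               c("ridge", "include_participant_intercepts", "maxit", "reltol"),
               "config$fit")
  config
}

config_params <- function(config) {
  if (is.null(config$params)) reference_params()
  else do.call(model_params, config$params)
}
config_latency <- function(config) {
  if (is.null(config$latency)) reference_latency()
  else do.call(latency_params, config$latency)
}
config_timing <- function(config) {
  if (is.null(config$timing)) timing_constants()
  else do.call(timing_constants, config$timing)
}
config_condition <- function(config) {
  sched <- if (is.null(config$schedule))
    schedule_spec("oet", threshold = 0.94)
  else do.call(schedule_spec, config$schedule)
  args <- if (is.null(config$condition)) list() else as.list(config$condition)
  args$schedule <- sched
  args$timing <- config_timing(config)
  do.call(sim_condition, args)
}
config_seed <- function(config, seed) {
  s <- if (!is.null(seed)) seed else if (!is.null(config$seed)) config$seed else 1L
  as.integer(s)
}

#' Pipeline commands
#'
#' Thin, file-oriented wrappers that tie the modules into a reproducible
#' pipeline; the \code{exec/oetsched} script exposes them as shell
#' subcommands (\code{generate}, \code{fit}, \code{simulate}, \code{sweep},
#' \code{report}), each taking \code{--config}, \code{--seed} and
#' \code{--out}.
#'
#' \code{cmd_generate} writes a synthetic trial log (\code{trial_log.csv})
#' plus the generating truth (\code{truth.json}); \code{cmd_fit} fits the
#' correctness and latency models to a trial log and writes
#' \code{fit.json}; \code{cmd_simulate} runs one condition and writes
#' \code{trials.csv}/\code{summary.csv}; \code{cmd_sweep} runs the OET
#' threshold sweep and writes \code{sweep.csv}; \code{cmd_report} computes
#' the condition analytics of a trial log and writes one tidy CSV per
#' diagnostic.
#'
#' @param config a configuration list from [read_run_config()] (or built in
#'   code).
#' @param seed optional integer overriding the config seed.
#' @param out_dir output directory, created if needed.
#' @param log_path for \code{cmd_fit}/\code{cmd_report}, path of the input
#'   trial-log CSV.
#' @return The main result object of each command, invisibly; files are
#'   written to \code{out_dir}.
#' @name pipeline
NULL

#' @rdname pipeline
#' @export
cmd_generate <- function(config = list(), seed = NULL, out_dir = ".") {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  design <- if (is.null(config$design)) study_design()
  else do.call(study_design, config$design)
  params <- config_params(config)
  latency <- config_latency(config)
  s <- config_seed(config, seed)
  noise <- if (is.null(config$rt_noise_sd)) 0.3 else config$rt_noise_sd
  tab <- generate_dataset(design, params, latency,
                          timing = config_timing(config),
                          rt_noise_sd = noise, seed = s)
  write_trial_log(tab, file.path(out_dir, "trial_log.csv"))
  jsonlite::write_json(list(params = unclass(params),
                            latency = unclass(latency),
                            design = unclass(design), seed = s),
                       file.path(out_dir, "truth.json"),
                       auto_unbox = TRUE, digits = NA, null = "null")
  invisible(tab)
}

#' @rdname pipeline
#' @export
cmd_fit <- function(log_path, config = list(), seed = NULL, out_dir = ".") {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  tab <- read_trial_log(log_path)
  options <- if (is.null(config$fit)) list() else config$fit
  fit <- fit_correctness(tab, options = options)
  if (!fit$convergence$outer_converged)
    stop("correctness fit did not converge: ", fit$convergence$message)
  feats <- fit$features
  ok <- feats$y == 1L & is.finite(feats$rt_s)
  lat <- if (sum(ok) >= 2L && stats::sd(stats::qlogis(fit$fitted_p[ok])) > 0)
    fit_latency(feats$rt_s[ok], stats::qlogis(fit$fitted_p[ok])) else NULL
  report <- list(
    params = unclass(fit$params),
    latency = if (!is.null(lat)) unclass(lat$params) else NULL,
    latency_sigma = if (!is.null(lat)) lat$sigma else NULL,
    include_participant_intercepts = fit$include_participant_intercepts,
    intercept_moments = fit$intercept_moments,
    log_lik = fit$log_lik, null_log_lik = fit$null_log_lik,
    mcfadden_r2 = fit$mcfadden_r2, auc = fit$auc,
    convergence = fit$convergence)
  jsonlite::write_json(report, file.path(out_dir, "fit.json"),
                       auto_unbox = TRUE, digits = NA, null = "null")
  invisible(fit)
}

#' @rdname pipeline
#' @export
cmd_simulate <- function(config = list(), seed = NULL, out_dir = ".") {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  cond <- config_condition(config)
  n_students <- if (is.null(config$n_students)) 200L else config$n_students
  res <- simulate_condition(cond, config_params(config),
                            config_latency(config),
                            n_students = n_students,
                            seed = config_seed(config, seed))
  tr <- condition_trials(res)
  tr <- tr[, c("student_id", "item_id", "trial_index", "clock_time_s",
               "kind", "predicted_p", "outcome", "duration_s")]
  utils::write.csv(tr, file.path(out_dir, "trials.csv"), row.names = FALSE,
                   quote = FALSE, na = "")
  utils::write.csv(condition_summary(res), file.path(out_dir, "summary.csv"),
                   row.names = FALSE, quote = FALSE, na = "")
  invisible(res)
}

#' @rdname pipeline
#' @export
cmd_sweep <- function(config = list(), seed = NULL, out_dir = ".") {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  cond <- config_condition(config)
  thresholds <- if (is.null(config$thresholds)) default_oet_grid()
  else as.numeric(config$thresholds)
  n_students <- if (is.null(config$n_students)) 200L else config$n_students
  sw <- oet_sweep(thresholds, cond, config_params(config),
                  config_latency(config), n_students = n_students,
                  seed = config_seed(config, seed))
  utils::write.csv(sw$table, file.path(out_dir, "sweep.csv"),
                   row.names = FALSE, quote = FALSE, na = "")
  invisible(sw)
}

#' @rdname pipeline
#' @export
cmd_report <- function(log_path, config = list(), seed = NULL,
                       out_dir = ".") {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  tr <- utils::read.csv(log_path, stringsAsFactors = FALSE)
  if (nrow(tr) == 0L) stop("trial log is empty")
  need <- c("student_id", "item_id", "trial_index", "kind", "outcome")
  miss <- setdiff(need, names(tr))
  if (length(miss) > 0)
    stop("trial log is missing columns: ", paste(miss, collapse = ", "))
  rr <- rolling_recall(tr)
  utils::write.csv(rr, file.path(out_dir, "rolling_recall.csv"),
                   row.names = FALSE, quote = FALSE, na = "")
  sp <- realized_spacing(tr)
  sp <- sp[!is.na(sp$spacing), ]
  utils::write.csv(sp, file.path(out_dir, "realized_spacing.csv"),
                   row.names = FALSE, quote = FALSE, na = "")
  counts <- stats::aggregate(trial_index ~ student_id, tr, length)
  names(counts)[2] <- "n_trials"
  utils::write.csv(counts, file.path(out_dir, "trial_counts.csv"),
                   row.names = FALSE, quote = FALSE, na = "")
  invisible(list(rolling_recall = rr, realized_spacing = sp,
                 trial_counts = counts))
}
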