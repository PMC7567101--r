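#' Simulation condition
#'
#' Full description of one simulated practice condition: the scheduling
#' policy, how trial durations are determined, the session time budget, the
#' item count, the retention interval before the final test, the timing
#' constants, and the alternate-assumption knobs.
#'
#' @param schedule a [schedule_spec()].
#' @param duration_mode \code{"latency_model"} (self-paced; correct trials
#'   faster) or \code{"fixed"} (every test trial takes
#'   \code{fixed_test_duration_s}).
#' @param session_budget_s practice-session time budget in seconds (default
#'   1320 s = 22 min; a trial is initiated only while elapsed time is below
#'   the budget, and an initiated trial completes fully).
#' @param n_items number of word pairs studied (default 30).
#' @param retention_s delay between session end and the final test (default
#'   259200 s = 3 days).
#' @param timing a [timing_constants()] object.
#' @param failure_gain_multiplier if a number \code{m}, the failure weight
#'   is overridden at condition setup as \eqn{\beta_2 = m\,\beta_1}
#'   (e.g. 1.25 makes failures 25\% more potent than successes); \code{NA}
#'   (the default) leaves the supplied parameters untouched.
#' @param final_test_mode \code{"expected"} scores the final test as the
#'   predicted recall probability per item (low variance); \code{"bernoulli"}
#'   samples one binary outcome per item.
#' @return An object of class \code{"sim_condition"}.
#' @export
sim_condition <- function(schedule,
                          duration_mode = c("latency_model", "fixed"),
                          session_budget_s = 1320,
                          n_items = 30L,
                          retention_s = 259200,
                          timing = timing_constants(),
                          failure_gain_multiplier = NA_real_,
                          final_test_mode = c("expected", "bernoulli")) {
  duration_mode <- match.arg(duration_mode)
  final_test_mode <- match.arg(final_test_mode)
  if (session_budget_s <= 0) stop("session_budget_s must be > 0")
  if (retention_s < 0) stop("retention_s must be >= 0")
  if (!is.na(failure_gain_multiplier) && failure_gain_multiplier <= 0)
    stop("failure_gain_multiplier must be > 0")
  structure(list(schedule = schedule, duration_mode = duration_mode,
                 session_budget_s = as.numeric(session_budget_s),
                 n_items = as.integer(n_items),
                 retention_s = as.numeric(retention_s),
                 timing = timing,
                 failure_gain_multiplier = failure_gain_multiplier,
                 final_test_mode = final_test_mode),
            class = "sim_condition")
}

apply_condition_knobs <- function(condition, params) {
  m <- condition$failure_gain_multiplier
  if (!is.na(m))
    params$beta_failure <- m * params$beta_success
  params
}

#' Sample a population of simulated students
#'
#' Draws student and per-student item intercepts independently from
#' Gaussian distributions and attaches a distinct sub-seed to each student,
#' so each simulated session has its own reproducible RNG stream.
#'
#' @param n_students number of students.
#' @param n_items number of items per student.
#' @param student_dist \code{c(mean, sd)} of the student-intercept Gaussian.
#' @param item_dist \code{c(mean, sd)} of the item-intercept Gaussian.
#' @param seed master integer seed.
#' @return A list of student specs, each a list with
#'   \code{student_intercept}, \code{item_intercepts} (length
#'   \code{n_items}) and \code{seed}.
#' @export
sample_population <- function(n_students, n_items,
                              student_dist = reference_intercept_dists()$student,
                              item_dist = reference_intercept_dists()$item,
                              seed = 1L) {
  if (student_dist[2] < 0 || item_dist[2] < 0) stop("sds must be >= 0")
  old <- .Random.seed_save(); on.exit(.Random.seed_restore(old))
  set.seed(as.integer(seed))
  s_int <- stats::rnorm(n_students, student_dist[1], student_dist[2])
  i_int <- matrix(stats::rnorm(n_students * n_items, item_dist[1], item_dist[2]),
                  nrow = n_students)
  seeds <- sample.int(.Machine$integer.max - 1L, n_students)
  lapply(seq_len(n_students), function(i) {
    list(student_intercept = s_int[i], item_intercepts = i_int[i, ],
         seed = seeds[i])
  })
}

#' Simulate one student's practice session and final test
#'
#' Runs a clock-accurate practice session.  While elapsed time is below the
#' session budget, the scheduler selects the next item; an item's first
#' exposure is a study trial, after which every attempt is a test whose
#' success is Bernoulli with the model's predicted recall probability.
#' Each trial is charged its duration (see [trial_duration()]) plus the
#' ISI.  After the session, a final test of every item is evaluated at
#' session end plus the retention interval.  For conventional kinds the
#' prebuilt fixed schedule is consumed in order, and its exhaustion before
#' the budget ends the session.
#'
#' @param condition a [sim_condition()].
#' @param params a [model_params()] object.
#' @param latency a [latency_params()] object.
#' @param student a student spec as produced by [sample_population()].
#' @return An object of class \code{"sim_result"}: a list with
#'   \code{trials} (the per-trial record), \code{final} (per-item final-test
#'   table), \code{elapsed_s}, \code{n_trials}, \code{student_intercept}
#'   and \code{item_intercepts}.
#' @export
simulate_student <- function(condition, params, latency, student) {
  params <- apply_condition_knobs(condition, params)
  tm <- condition$timing
  n_items <- condition$n_items
  kind <- condition$schedule$kind
  old <- .Random.seed_save(); on.exit(.Random.seed_restore(old))
  set.seed(as.integer(student$seed))

  bs <- params$beta_success; bf <- params$beta_failure
  ds <- params$decay_success; df_ <- params$decay_failure
  cc <- params$spacing_curvature
  base_eta <- student$student_intercept + student$item_intercepts

  # incremental per-item history state
  n_ev <- integer(n_items); n_s <- numeric(n_items); n_f <- numeric(n_items)
  first_t <- rep(NA_real_, n_items); last_t <- rep(NA_real_, n_items)
  gap_sum <- numeric(n_items)

  predict_all <- function(now) {
    age <- pmax(1, now - first_t)
    S <- ifelse(n_ev >= 2L, pmax(1, gap_sum / pmax(1L, n_ev - 1L)), 1)
    sc <- S^cc
    act <- bs * n_s * age^(-ds) * sc + bf * n_f * age^(-df_) * sc
    act[n_ev == 0L] <- 0
    p <- logistic(act + base_eta)
    pmin(pmax(p, 1e-12), 1 - 1e-12)
  }

  fixed_seq <- NULL; d1 <- NULL; last_outcome <- NULL
  if (kind %in% c("massed", "uniform", "expanding", "contracting",
                  "blocked_s15")) {
    fixed_seq <- build_fixed_schedule(n_items, condition$schedule,
                                      seed = student$seed)
  } else if (kind == "drop1") {
    d1 <- drop1_state(seq_len(n_items), seed = student$seed)
  }

  cap <- 4096L
  r_item <- integer(cap); r_kind <- character(cap); r_out <- character(cap)
  r_p <- numeric(cap); r_t <- numeric(cap); r_dur <- numeric(cap)

  clock <- 0; k <- 0L
  while (clock < condition$session_budget_s) {
    if (!is.null(fixed_seq)) {
      if (k >= length(fixed_seq)) break
      item <- fixed_seq[k + 1L]
      p_all <- NULL
    } else if (kind == "drop1") {
      sel <- next_item_drop1(d1, last_outcome)
      item <- sel$item; d1 <- sel$state
      p_all <- NULL
    } else {                                     # oet
      p_all <- predict_all(clock)
      item <- next_item_oet(p_all, condition$schedule$threshold)
    }
    k <- k + 1L
    if (k > cap) {
      cap <- cap * 2L
      length(r_item) <- cap; length(r_kind) <- cap; length(r_out) <- cap
      length(r_p) <- cap; length(r_t) <- cap; length(r_dur) <- cap
    }
    if (n_ev[item] == 0L) {
      tkind <- "study"; outcome <- "none"; p <- NA_real_
      dur <- tm$study_duration_s
    } else {
      tkind <- "test"
      p <- if (!is.null(p_all)) p_all[item] else predict_all(clock)[item]
      outcome <- if (stats::runif(1) < p) "success" else "failure"
      dur <- trial_duration("test", outcome, log_odds = stats::qlogis(p),
                            mode = condition$duration_mode, timing = tm,
                            params = latency)
    }
    # update history state (event at trial onset)
    if (n_ev[item] > 0L) gap_sum[item] <- gap_sum[item] + (clock - last_t[item])
    if (n_ev[item] == 0L) first_t[item] <- clock
    last_t[item] <- clock
    n_ev[item] <- n_ev[item] + 1L
    if (tkind == "study" || outcome == "success") n_s[item] <- n_s[item] + 1
    if (outcome == "failure") n_f[item] <- n_f[item] + 1
    last_outcome <- outcome

    r_item[k] <- item; r_kind[k] <- tkind; r_out[k] <- outcome
    r_p[k] <- p; r_t[k] <- clock; r_dur[k] <- dur
    clock <- clock + dur + tm$isi_s
  }

  trials <- data.frame(item_id = r_item[seq_len(k)],
                       trial_index = seq_len(k),
                       clock_time_s = r_t[seq_len(k)],
                       kind = r_kind[seq_len(k)],
                       predicted_p = r_p[seq_len(k)],
                       outcome = r_out[seq_len(k)],
                       duration_s = r_dur[seq_len(k)],
                       stringsAsFactors = FALSE)

  test_time <- clock + condition$retention_s
  p_final <- predict_all(test_time)
  final <- data.frame(item_id = seq_len(n_items), p_recall = p_final,
                      stringsAsFactors = FALSE)
  if (condition$final_test_mode == "bernoulli")
    final$outcome <- as.integer(stats::runif(n_items) < p_final)

  structure(list(trials = trials, final = final, elapsed_s = clock,
                 n_trials = k,
                 student_intercept = student$student_intercept,
                 item_intercepts = student$item_intercepts),
            class = "sim_result")
}

#' Simulate a full condition over a population
#'
#' Simulates \code{n_students} independent students (sub-seeds derived from
#' the master seed) under one condition and summarizes the final test:
#' the mean over students of the per-student mean item recall, with its
#' standard error across students (absent when \code{n_students == 1}).
#'
#' @inheritParams simulate_student
#' @param n_students number of simulated students (default 200).
#' @param seed master seed; the derived per-student seeds make results
#'   bit-reproducible.
#' @param population optionally, a pre-sampled population from
#'   [sample_population()] (used by [oet_sweep()] for common random
#'   numbers); overrides \code{n_students} and \code{seed}.
#' @return An object of class \code{"condition_result"}: list with
#'   \code{results} (per-student [simulate_student()] outputs) and
#'   \code{summary} (mean recall, SEM, mean trials, mean elapsed time).
#' @export
simulate_condition <- function(condition, params, latency,
                               n_students = 200L, seed = 1L,
                               population = NULL) {
  if (is.null(population))
    population <- sample_population(n_students, condition$n_items, seed = seed)
  results <- lapply(population, function(st)
    simulate_student(condition, params, latency, st))
  per_student <- vapply(results, function(r) mean(r$final$p_recall), 0)
  n <- length(results)
  summary <- list(
    mean_recall = mean(per_student),
    sem = if (n > 1L) stats::sd(per_student) / sqrt(n) else NA_real_,
    mean_trials = mean(vapply(results, `[[`, 0, "n_trials")),
    mean_elapsed_s = mean(vapply(results, `[[`, 0, "elapsed_s")))
  structure(list(results = results, summary = summary, condition = condition),
            class = "condition_result")
}

#' @export
print.condition_result <- function(x, ...) {
  s <- x$summary
  cat(sprintf("Condition '%s': mean final recall %.3f (SEM %s), %.1f trials, %.0f s\n",
              x$condition$schedule$kind, s$mean_recall,
              ifelse(is.na(s$sem), "NA", sprintf("%.3f", s$sem)),
              s$mean_trials, s$mean_elapsed_s))
  invisible(x)
}

#' Default OET threshold grid
#'
#' The 22-value sweep grid: steps of 0.05 from 0.20 to 0.80 and steps of
#' 0.02 from 0.80 onward to 0.98.
#'
#' @return Numeric vector of 22 thresholds.
#' @export
default_oet_grid <- function() {
  unique(c(seq(0.20, 0.80, by = 0.05), seq(0.82, 0.98, by = 0.02)))
}

#' Sweep the OET threshold grid
#'
#' Simulates the adaptive policy across a grid of recall-probability
#' thresholds.  By default the same population (common random numbers) is
#' reused for every threshold to sharpen between-condition contrasts.
#'
#' @param thresholds numeric vector of thresholds in (0, 1); defaults to
#'   [default_oet_grid()].
#' @param base_condition a [sim_condition()] whose schedule field is
#'   replaced by an OET schedule at each threshold (any kind accepted).
#' @inheritParams simulate_condition
#' @param common_random logical; reuse one population across thresholds
#'   (default) or draw an independent population per threshold.
#' @return An object of class \code{"oet_sweep"}: list with \code{table}
#'   (threshold, mean_recall, sem, mean_trials), \code{best_threshold}, and
#'   \code{results} (per-threshold condition results).
#' @export
oet_sweep <- function(thresholds = default_oet_grid(), base_condition,
                      params, latency, n_students = 200L, seed = 1L,
                      common_random = TRUE) {
  if (any(thresholds <= 0 | thresholds >= 1))
    stop("thresholds must lie strictly inside (0, 1)")
  population <- if (common_random)
    sample_population(n_students, base_condition$n_items, seed = seed)
  results <- vector("list", length(thresholds))
  for (i in seq_along(thresholds)) {
    cond <- base_condition
    cond$schedule <- schedule_spec("oet", threshold = thresholds[i])
    pop_i <- if (common_random) population else
      sample_population(n_students, cond$n_items,
                        seed = as.integer(seed) + i)
    results[[i]] <- simulate_condition(cond, params, latency,
                                       population = pop_i)
  }
  tab <- data.frame(
    threshold = thresholds,
    mean_recall = vapply(results, function(r) r$summary$mean_recall, 0),
    sem = vapply(results, function(r) r$summary$sem, 0),
    mean_trials = vapply(results, function(r) r$summary$mean_trials, 0))
  structure(list(table = tab,
                 best_threshold = thresholds[which.max(tab$mean_recall)],
                 results = results),
            class = "oet_sweep")
}

#' @export
print.oet_sweep <- function(x, ...) {
  cat("OET threshold sweep:\n")
  print(x$table, row.names = FALSE, digits = 4)
  cat(sprintf("Best threshold: %.2f\n", x$best_threshold))
  invisible(x)
}

#' Final-test evaluation of a set of item histories
#'
#' Evaluates every item's recall at a (later) test time, either as the
#' model's expected probability or as one Bernoulli draw per item.
#'
#' @param histories list of [item_history()] objects (possibly empty
#'   histories for never-practiced items).
#' @param params a [model_params()] object.
#' @param intercepts either a single [intercept_set()] applied to all items
#'   or a list of one per item.
#' @param test_time_s evaluation time; must not precede any history's last
#'   event.
#' @param mode \code{"expected"} or \code{"bernoulli"}.
#' @return Data frame with \code{item_id}, \code{p_recall} and, in
#'   bernoulli mode, \code{outcome}.
#' @export
final_test <- function(histories, params, intercepts, test_time_s,
                       mode = c("expected", "bernoulli")) {
  mode <- match.arg(mode)
  single <- inherits(intercepts, "intercept_set")
  p <- vapply(seq_along(histories), function(i) {
    ic <- if (single) intercepts else intercepts[[i]]
    predict_recall(compute_features(histories[[i]], test_time_s), params, ic)
  }, 0)
  out <- data.frame(item_id = seq_along(histories), p_recall = p)
  if (mode == "bernoulli")
    out$outcome <- as.integer(stats::runif(length(p)) < p)
  out
}
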