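# Combined per-trial table for a condition_result, with student ids and
# intercepts attached.
condition_trials <- function(condres) {
  stopifnot(inherits(condres, "condition_result"))
  do.call(rbind, lapply(seq_along(condres$results), function(i) {
    tr <- condres$results[[i]]$trials
    tr$student_id <- i
    tr
  }))
}

# 5th percentile (type 1) of per-student counts: the count reached by 95%
# of students.
attained_by_95 <- function(counts) {
  as.integer(stats::quantile(counts, 0.05, type = 1))
}

#' Rolling recall probability across practice
#'
#' Moving average (default window 5) of test-trial correctness by test
#' position, averaged across students, truncated at the number of test
#' trials completed by 95\% of students.  This is the "achieved
#' probability" diagnostic: what difficulty the schedule actually delivered
#' at each point in practice.
#'
#' @param records combined trial records (a \code{condition_result} or a
#'   data frame with \code{student_id}, \code{kind}, \code{outcome},
#'   \code{trial_index}).
#' @param window moving-average window in test trials (default 5).
#' @return Data frame with \code{test_index}, \code{rolling_recall},
#'   \code{n_students}; zero rows if no student completes \code{window}
#'   test trials.
#' @export
rolling_recall <- function(records, window = 5L) {
  if (window < 1L) stop("window must be >= 1")
  tr <- if (inherits(records, "condition_result"))
    condition_trials(records) else records
  tests <- tr[tr$kind == "test", ]
  if (nrow(tests) == 0L)
    return(data.frame(test_index = integer(), rolling_recall = numeric(),
                      n_students = integer()))
  tests <- tests[order(tests$student_id, tests$trial_index), ]
  y <- as.numeric(tests$outcome == "success")
  idx <- stats::ave(seq_len(nrow(tests)), tests$student_id, FUN = seq_along)
  counts <- tapply(idx, tests$student_id, max)
  cut <- attained_by_95(counts)
  if (cut < window)
    return(data.frame(test_index = integer(), rolling_recall = numeric(),
                      n_students = integer()))
  roll <- stats::ave(y, tests$student_id, FUN = function(v) {
    r <- stats::filter(v, rep(1 / window, window), sides = 1)
    as.numeric(r)
  })
  keep <- idx >= window & idx <= cut
  agg <- stats::aggregate(roll[keep], list(test_index = idx[keep]),
                          function(v) c(mean(v), length(v)))
  data.frame(test_index = agg$test_index,
             rolling_recall = agg$x[, 1], n_students = as.integer(agg$x[, 2]))
}

# realized intervening-trial gaps per student-item attempt
realized_spacing <- function(tr) {
  tr <- tr[order(tr$student_id, tr$item_id, tr$trial_index), ]
  g <- interaction(tr$student_id, tr$item_id, drop = TRUE)
  attempt <- stats::ave(seq_len(nrow(tr)), g, FUN = seq_along)
  prev_idx <- stats::ave(tr$trial_index, g,
                         FUN = function(x) c(NA, x[-length(x)]))
  data.frame(student_id = tr$student_id, item_id = tr$item_id,
             attempt = attempt, trial_index = tr$trial_index,
             spacing = tr$trial_index - prev_idx - 1L)
}

#' Item difficulty versus realized spacing
#'
#' For every student-item pair with at least two attempts, the mean
#' realized spacing (intervening trials between consecutive attempts)
#' against the item's intercept, with an OLS slope.  Under an adaptive
#' threshold policy easier items (higher intercepts) earn wider spacing.
#'
#' @param condres a \code{condition_result} from [simulate_condition()].
#' @return List with \code{table} (student_id, item_id, item_intercept,
#'   mean_spacing) and \code{slope} (OLS slope of mean spacing on
#'   intercept; \code{NA} with a note if the intercepts are degenerate).
#' @export
spacing_vs_difficulty <- function(condres) {
  tr <- condition_trials(condres)
  sp <- realized_spacing(tr)
  sp <- sp[!is.na(sp$spacing), ]
  if (nrow(sp) == 0L) stop("need items with at least 2 attempts")
  agg <- stats::aggregate(spacing ~ student_id + item_id, sp, mean)
  names(agg)[3] <- "mean_spacing"
  agg$item_intercept <- vapply(seq_len(nrow(agg)), function(r)
    condres$results[[agg$student_id[r]]]$item_intercepts[agg$item_id[r]], 0)
  slope <- if (stats::sd(agg$item_intercept) == 0) NA_real_ else
    unname(stats::coef(stats::lm(mean_spacing ~ item_intercept, agg))[2])
  list(table = agg, slope = slope)
}

#' Spacing by attempt number
#'
#' Mean realized intervening-trial spacing at each attempt number,
#' truncated at the attempt count reached by 95\% of students, with an OLS
#' trend slope.  A positive slope is the signature of a naturally expanding
#' schedule.
#'
#' @param condres a \code{condition_result}.
#' @return List with \code{table} (attempt, mean_spacing, n) and
#'   \code{slope}; zero-row table when no item has two attempts.
#' @export
spacing_by_attempt <- function(condres) {
  tr <- condition_trials(condres)
  sp <- realized_spacing(tr)
  sp <- sp[!is.na(sp$spacing), ]
  if (nrow(sp) == 0L)
    return(list(table = data.frame(attempt = integer(),
                                   mean_spacing = numeric(), n = integer()),
                slope = NA_real_))
  max_attempt <- tapply(sp$attempt, sp$student_id, max)
  cut <- attained_by_95(max_attempt)
  sp <- sp[sp$attempt <= cut, ]
  agg <- stats::aggregate(spacing ~ attempt, sp,
                          function(v) c(mean(v), length(v)))
  tab <- data.frame(attempt = agg$attempt, mean_spacing = agg$spacing[, 1],
                    n = as.integer(agg$spacing[, 2]))
  slope <- if (nrow(tab) < 2L) NA_real_ else
    unname(stats::coef(stats::lm(mean_spacing ~ attempt, tab))[2])
  list(table = tab, slope = slope)
}

#' Trial count versus student ability
#'
#' Pearson correlation between the student intercept (ability) and the
#' number of trials completed.  In self-paced conventional schedules better
#' students complete more trials; an adaptive threshold policy keeps
#' difficulty, and hence trial counts, roughly even across abilities.
#'
#' @param condres a \code{condition_result} with at least 3 students.
#' @return List with \code{table} (student_id, student_intercept, n_trials),
#'   \code{correlation} (\code{NA} with a note when trial counts are
#'   constant), and \code{note}.
#' @export
trials_vs_student_intercept <- function(condres) {
  n <- length(condres$results)
  if (n < 3L) stop("need at least 3 students")
  tab <- data.frame(
    student_id = seq_len(n),
    student_intercept = vapply(condres$results, `[[`, 0, "student_intercept"),
    n_trials = vapply(condres$results, `[[`, 0, "n_trials"))
  if (stats::sd(tab$n_trials) == 0 || stats::sd(tab$student_intercept) == 0) {
    list(table = tab, correlation = NA_real_,
         note = "zero variance: correlation undefined")
  } else {
    list(table = tab,
         correlation = stats::cor(tab$student_intercept, tab$n_trials),
         note = "ok")
  }
}

#' Condition summary table
#'
#' One-row summary of a simulated condition: mean final-test recall, its
#' SEM across students, mean trials per student and mean session time.
#'
#' @param condres a \code{condition_result}.
#' @param label condition label for the output row.
#' @return One-row data frame.
#' @export
condition_summary <- function(condres, label = condres$condition$schedule$kind) {
  s <- condres$summary
  data.frame(condition = label,
             threshold = if (!is.null(condres$condition$schedule$threshold))
               condres$condition$schedule$threshold else NA_real_,
             mean_recall = s$mean_recall, sem = s$sem,
             mean_trials = s$mean_trials,
             mean_elapsed_s = s$mean_elapsed_s,
             stringsAsFactors = FALSE)
}
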