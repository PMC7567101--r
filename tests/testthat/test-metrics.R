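# a hand-built condition_result with two students and known trial patterns
fake_condres <- function() {
  mk <- function(items, kinds, outs, s_int, i_int) {
    trials <- data.frame(item_id = items, trial_index = seq_along(items),
                         clock_time_s = cumsum(rep(10, length(items))),
                         kind = kinds, predicted_p = 0.5, outcome = outs,
                         duration_s = 9, stringsAsFactors = FALSE)
    structure(list(trials = trials,
                   final = data.frame(item_id = unique(items), p_recall = 0.5),
                   elapsed_s = 10 * length(items), n_trials = length(items),
                   student_intercept = s_int, item_intercepts = i_int),
              class = "sim_result")
  }
  r1 <- mk(c(1, 2, 1, 2, 1, 2), c("study", "study", rep("test", 4)),
           c("none", "none", "success", "failure", "success", "success"),
           0.5, c(0.2, -0.3))
  r2 <- mk(c(1, 1, 1, 2, 2, 2), c("study", rep("test", 2), "study", rep("test", 2)),
           c("none", "success", "failure", "none", "failure", "failure"),
           -0.5, c(0.1, -0.1))
  structure(list(results = list(r1, r2),
                 summary = list(mean_recall = 0.5, sem = 0, mean_trials = 6,
                                mean_elapsed_s = 60),
                 condition = sim_condition(schedule_spec("oet", threshold = 0.9),
                                           n_items = 2L)),
            class = "condition_result")
}

test_that("rolling recall is the windowed mean of test outcomes", {
  tr <- data.frame(student_id = 1, trial_index = 1:5, kind = "test",
                   outcome = c("success", "success", "failure", "success",
                               "success"))
  rr <- rolling_recall(tr, window = 5)
  expect_equal(rr$rolling_recall[rr$test_index == 5], 0.8)
  # window 1 returns the raw per-index mean
  rr1 <- rolling_recall(tr, window = 1)
  expect_equal(rr1$rolling_recall,
               as.numeric(tr$outcome == "success"))
  # fewer trials than the window: empty series
  expect_equal(nrow(rolling_recall(tr[1:3, ], window = 5)), 0L)
  expect_error(rolling_recall(tr, window = 0), "window")
})

test_that("rolling recall truncates at the trial count reached by 95% of students", {
  set.seed(6)
  tr <- do.call(rbind, lapply(1:40, function(s) {
    n <- if (s == 1) 4L else 20L   # one straggler
    data.frame(student_id = s, trial_index = seq_len(n), kind = "test",
               outcome = sample(c("success", "failure"), n, TRUE))
  }))
  rr <- rolling_recall(tr, window = 2)
  counts <- c(4L, rep(20L, 39))
  expect_equal(max(rr$test_index),
               as.integer(stats::quantile(counts, 0.05, type = 1)))
})

test_that("spacing diagnostics recount gaps exactly on a hand-built log", {
  cr <- fake_condres()
  sp <- oetsched:::realized_spacing(oetsched:::condition_trials(cr))
  # student 1, item 1 at positions 1,3,5: gaps 1 and 1
  s1 <- sp[sp$student_id == 1 & sp$item_id == 1 & !is.na(sp$spacing), ]
  expect_equal(s1$spacing, c(1, 1))
  # student 2, item 1 at positions 1,2,3: gaps 0
  s2 <- sp[sp$student_id == 2 & sp$item_id == 1 & !is.na(sp$spacing), ]
  expect_equal(s2$spacing, c(0, 0))
  svd <- spacing_vs_difficulty(cr)
  expect_equal(nrow(svd$table), 4L)
  expect_true(is.finite(svd$slope))
})

test_that("spacing-by-attempt is flat for an unjittered uniform schedule", {
  cond <- sim_condition(schedule_spec("uniform", 4, reps_per_item = 5),
                        duration_mode = "fixed", n_items = 10L)
  cr <- simulate_condition(cond, reference_params(), reference_latency(),
                           n_students = 5, seed = 12)
  sba <- spacing_by_attempt(cr)
  expect_true(all(abs(sba$table$mean_spacing - 4) < 1e-9))
  expect_equal(sba$slope, 0, tolerance = 1e-9)
})

test_that("trial-count/ability correlation handles constant counts", {
  cond <- sim_condition(schedule_spec("uniform", 4, reps_per_item = 4),
                        duration_mode = "fixed", n_items = 10L)
  cr <- simulate_condition(cond, reference_params(), reference_latency(),
                           n_students = 6, seed = 13)
  tvi <- trials_vs_student_intercept(cr)
  expect_true(is.na(tvi$correlation))
  expect_match(tvi$note, "zero variance")
  expect_error(trials_vs_student_intercept(
    structure(list(results = cr$results[1:2]), class = "condition_result")),
    "at least 3")
})

test_that("condition summaries carry the headline statistics", {
  cr <- fake_condres()
  cs <- condition_summary(cr, label = "toy")
  expect_equal(cs$condition, "toy")
  expect_equal(cs$mean_recall, 0.5)
  expect_equal(cs$threshold, 0.9)
})
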