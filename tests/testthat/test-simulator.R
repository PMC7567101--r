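test_that("fixed-duration conventional sessions reproduce the standard arithmetic", {
  # 30 items x 4 reps: 30 study trials (7 s) + 90 tests (11 s) + 120 ISIs
  # (1 s) = 1320 s in exactly 120 trials
  cond <- sim_condition(schedule_spec("uniform", 15, reps_per_item = 4),
                        duration_mode = "fixed")
  st <- sample_population(1, 30, seed = 5)[[1]]
  r <- simulate_student(cond, reference_params(), reference_latency(), st)
  expect_equal(r$n_trials, 120L)
  expect_equal(r$elapsed_s, 1320)
  expect_equal(sum(r$trials$kind == "study"), 30L)
})

test_that("a degenerate model predicts 0.5 everywhere with zero intercepts", {
  null <- model_params(0, 0, 0.2, 0.3, 0.1)
  st <- list(student_intercept = 0, item_intercepts = rep(0, 10), seed = 77L)
  cond <- sim_condition(schedule_spec("uniform", 4, reps_per_item = 4),
                        n_items = 10L, duration_mode = "fixed")
  r <- simulate_student(cond, null, reference_latency(), st)
  tests <- r$trials[r$trials$kind == "test", ]
  expect_true(all(tests$predicted_p == 0.5))
  expect_true(all(r$final$p_recall == 0.5))
})

test_that("simulation is bit-reproducible under a fixed seed", {
  cond <- sim_condition(schedule_spec("oet", threshold = 0.9), n_items = 10L)
  st <- tiny_population()[[1]]
  r1 <- simulate_student(cond, reference_params(), reference_latency(), st)
  r2 <- simulate_student(cond, reference_params(), reference_latency(), st)
  expect_identical(r1, r2)
  c1 <- simulate_condition(cond, reference_params(), reference_latency(),
                           n_students = 4, seed = 9)
  c2 <- simulate_condition(cond, reference_params(), reference_latency(),
                           n_students = 4, seed = 9)
  expect_identical(c1$summary, c2$summary)
})

test_that("time budget is conserved up to one trial overrun", {
  cond <- sim_condition(schedule_spec("oet", threshold = 0.9), n_items = 10L)
  max_span <- with(timing_constants(),
                   max(study_duration_s,
                       max_response_s + correct_feedback_s,
                       failure_response_s + failure_feedback_s) + isi_s)
  for (st in tiny_population(8)) {
    r <- simulate_student(cond, reference_params(), reference_latency(), st)
    expect_equal(r$elapsed_s, sum(r$trials$duration_s) + r$n_trials * 1)
    expect_gte(r$elapsed_s, cond$session_budget_s - max_span)
    expect_lte(r$elapsed_s, cond$session_budget_s + max_span)
  }
})

test_that("population sampling is reproducible with correct moments", {
  pop <- sample_population(200, 5, c(0, 1), c(-2, 1), seed = 1)
  expect_length(pop, 200)
  expect_length(unique(vapply(pop, `[[`, 0L, "seed")), 200L)
  big <- sample_population(10000, 2, c(0.3, 0.9), c(-1, 0.5), seed = 2)
  s <- vapply(big, `[[`, 0, "student_intercept")
  expect_lt(abs(mean(s) - 0.3), 3 * 0.9 / sqrt(10000))
  expect_lt(abs(stats::sd(s) - 0.9), 3 * 0.9 / sqrt(2 * 10000))
  degen <- sample_population(5, 3, c(0.7, 0), c(0.1, 0), seed = 3)
  expect_true(all(vapply(degen, `[[`, 0, "student_intercept") == 0.7))
})

test_that("retention-free final tests beat delayed ones when forgetting is on", {
  base <- sim_condition(schedule_spec("oet", threshold = 0.9), n_items = 10L,
                        retention_s = 0)
  delayed <- base; delayed$retention_s <- 259200
  pop <- tiny_population(10)
  p <- reference_params()
  for (st in pop) {
    r0 <- simulate_student(base, p, reference_latency(), st)
    r3 <- simulate_student(delayed, p, reference_latency(), st)
    expect_gt(mean(r0$final$p_recall), mean(r3$final$p_recall))
  }
})

test_that("the default sweep grid has the canonical 22 thresholds", {
  g <- default_oet_grid()
  expect_length(g, 22L)
  expect_equal(min(g), 0.2)
  expect_equal(max(g), 0.98)
  expect_equal(sum(g <= 0.8), 13L)   # 0.05 steps to 0.8, 0.02 beyond
})

test_that("single-threshold sweeps and single students degenerate gracefully", {
  cond <- sim_condition(schedule_spec("oet", threshold = 0.9), n_items = 8L)
  sw <- oet_sweep(0.5, cond, reference_params(), reference_latency(),
                  n_students = 3, seed = 2)
  expect_equal(nrow(sw$table), 1L)
  expect_equal(sw$best_threshold, 0.5)
  one <- simulate_condition(cond, reference_params(), reference_latency(),
                            n_students = 1, seed = 4)
  expect_true(is.na(one$summary$sem))
})

test_that("final_test scores histories at the requested time", {
  p <- model_params(1, 0.5, 0.2, 0.3, 0.1)
  hs <- list(item_history(), toy_history())
  ft <- final_test(hs, p, intercept_set(0, 0), test_time_s = 3600)
  expect_equal(ft$p_recall[1], 0.5)   # never practiced, zero intercepts
  expect_equal(ft$p_recall[2],
               predict_recall(compute_features(toy_history(), 3600), p,
                              intercept_set(0, 0)))
  # bernoulli mode agrees with expected mode in the mean
  set.seed(8)
  draws <- replicate(4000, final_test(hs[2], p, intercept_set(0, 0), 3600,
                                      mode = "bernoulli")$outcome)
  expect_lt(abs(mean(draws) - ft$p_recall[2]),
            3 * sqrt(ft$p_recall[2] * (1 - ft$p_recall[2]) / 4000))
})

test_that("the failure-gain knob rescales the failure weight at setup", {
  cond <- sim_condition(schedule_spec("oet", threshold = 0.9),
                        failure_gain_multiplier = 1.25)
  p <- model_params(0.8, 0.1, 0.2, 0.3, 0.1)
  p2 <- oetsched:::apply_condition_knobs(cond, p)
  expect_equal(p2$beta_failure, 1.25 * 0.8)
  cond_off <- sim_condition(schedule_spec("oet", threshold = 0.9))
  expect_equal(oetsched:::apply_condition_knobs(cond_off, p)$beta_failure, 0.1)
})
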