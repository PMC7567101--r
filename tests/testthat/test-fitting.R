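test_that("AUC matches exhaustive pair counting and pROC", {
  expect_equal(auc(c(0.9, 0.8, 0.3, 0.2), c(1, 0, 1, 0)), 0.75)
  expect_equal(auc(c(0.9, 0.8, 0.3, 0.2), c(1, 1, 0, 0)), 1.0)
  expect_equal(auc(rep(0.5, 10), rep(c(0, 1), 5)), 0.5)  # pure ties
  expect_error(auc(c(0.2, 0.4), c(1, 1)), "both")
  skip_if_not_installed("pROC")
  set.seed(14)
  for (i in 1:20) {
    pr <- stats::runif(60)
    y <- stats::rbinom(60, 1, pr)
    if (length(unique(y)) < 2) next
    ref <- as.numeric(pROC::auc(pROC::roc(y, pr, quiet = TRUE,
                                          direction = "<")))
    expect_equal(auc(pr, y), ref, tolerance = 1e-10)
  }
})

test_that("trial features agree with per-history recomputation", {
  tab <- generate_dataset(study_design(n_participants = 3L),
                          seed = 42)
  feats <- trial_features(tab)
  set.seed(2)
  pick <- sample(nrow(feats), 40)
  for (r in pick) {
    row <- feats[r, ]
    ev <- tab[tab$student_id == row$student_id &
                tab$item_id == row$item_id &
                tab$time_s < row$time_s, ]
    h <- item_history(ev$time_s, ev$kind, ev$outcome)
    want <- compute_features(h, row$time_s)
    expect_equal(row$n_success, as.numeric(want$n_success))
    expect_equal(row$n_failure, as.numeric(want$n_failure))
    expect_equal(row$age_s, want$age_s)
    # features use the history *before* the trial, so spacing is the mean
    # gap among prior events
    prior_gaps <- diff(ev$time_s)
    want_S <- if (length(prior_gaps) >= 1 && nrow(ev) >= 2)
      max(1, mean(prior_gaps)) else 1
    expect_equal(row$mean_spacing_s, want_S)
  }
})

test_that("the penalized logistic inner solver matches glm without penalty", {
  set.seed(31)
  n <- 400
  x1 <- stats::rnorm(n); x2 <- stats::rnorm(n)
  g <- factor(sample(letters[1:4], n, TRUE))
  eta <- 0.8 * x1 - 0.5 * x2 + c(a = -1, b = 0, c = 0.5, d = 1)[g]
  y <- stats::rbinom(n, 1, stats::plogis(eta))
  X <- Matrix::sparse.model.matrix(~ 0 + x1 + x2 + g)
  ours <- oetsched:::penalized_logistic(X, y, n_free = 2L, ridge = 0)
  ref <- stats::glm(y ~ 0 + x1 + x2 + g, family = stats::binomial())
  expect_equal(unname(ours$coef), unname(stats::coef(ref)), tolerance = 1e-6)
  expect_equal(ours$log_lik, as.numeric(stats::logLik(ref)), tolerance = 1e-8)
})

test_that("correctness fitting recovers parameters from a small synthetic study", {
  truth <- recovery_truth()
  tab <- generate_dataset(study_design(n_participants = 60L), truth,
                          seed = 99)
  fit <- fit_correctness(tab, options = list(maxit = 300L))
  expect_true(fit$convergence$outer_converged)
  expect_gte(fit$log_lik, fit$null_log_lik)
  expect_gte(fit$mcfadden_r2, 0)
  expect_gt(fit$auc, 0.6)
  rep <- parameter_recovery_report(truth, fit)
  expect_lt(rep$rel_error[rep$parameter == "beta_success"], 0.35)
  expect_lt(rep$abs_error[rep$parameter == "decay_success"], 0.1)
  expect_lt(rep$abs_error[rep$parameter == "spacing_curvature"], 0.15)
  # intercept moments are estimated near the generating distributions
  # (students centered at 0, the level carried by the item block)
  expect_equal(fit$intercept_moments$student[["mean"]], 0)
  expect_lt(abs(fit$intercept_moments$item[["mean"]] - (-2.5)), 0.6)
  expect_lt(abs(fit$intercept_moments$student[["sd"]] - 1), 0.3)
})

test_that("item-only refits drop the participant intercepts", {
  tab <- generate_dataset(study_design(n_participants = 20L), seed = 17)
  fit <- fit_correctness(tab, options = list(
    include_participant_intercepts = FALSE, maxit = 150L))
  expect_null(fit$student_intercepts)
  expect_false(fit$include_participant_intercepts)
  expect_equal(length(fit$item_intercepts), 48L)
})

test_that("a dataset with no failures flags the failure weight as unidentifiable", {
  # all-success logs carry no information about the failure component
  tab <- data.frame(
    student_id = rep(1:4, each = 6),
    item_id = rep(rep(1:2, each = 3), 4),
    time_s = rep(c(0, 30, 60, 1000, 1030, 1060), 4),
    kind = rep(c("study", "test", "test"), 8),
    outcome = rep(c("none", "success", "success"), 8),
    rt_s = NA_real_)
  fit <- fit_correctness(tab, options = list(maxit = 50L))
  expect_false(fit$convergence$beta_failure_identifiable)
  expect_error(fit_correctness(tab[0, ]), "empty|columns")
})

test_that("latency fitting recovers parameters exactly from noiseless data", {
  lo <- seq(-2, 4, length.out = 50)
  rt <- predict_rt(lo, latency_params(3, 1.5))
  fit <- fit_latency(rt, lo)
  expect_equal(fit$params$rt_scale, 3, tolerance = 1e-4)
  expect_equal(fit$params$rt_floor, 1.5, tolerance = 1e-4)
})

test_that("latency fitting recovers parameters from noisy data within 5%", {
  set.seed(4)
  lo <- stats::rnorm(5000, 1, 1.5)
  rt <- predict_rt(lo, latency_params(3, 1.5)) + stats::rnorm(5000, 0, 0.3)
  fit <- fit_latency(rt, lo)
  expect_lt(abs(fit$params$rt_scale - 3) / 3, 0.05)
  expect_lt(abs(fit$params$rt_floor - 1.5) / 1.5, 0.05)
  # log-normal option also runs and lands close
  fit2 <- fit_latency(pmax(rt, 0.2), lo, noise = "lognormal")
  expect_lt(abs(fit2$params$rt_scale - 3) / 3, 0.2)
})

test_that("degenerate latency designs are rejected or flagged", {
  expect_error(fit_latency(c(2, 2, 2), c(1, 1, 1)), "degenerate")
  # constant RT at huge log-odds: floor absorbs everything, scale at bound
  lo <- c(20, 21, 22, 23)
  fit <- fit_latency(rep(2.5, 4), lo)
  expect_equal(fit$params$rt_floor, 2.5, tolerance = 1e-3)
  expect_true(fit$boundary)
})
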