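test_that("study designs validate cell divisibility and retention counts", {
  expect_error(study_design(items_per_participant = 50L), "divide equally")
  expect_silent(study_design())
  expect_error(study_design(retention_counts = c(10, 10)), "retention_counts")
})

test_that("generated datasets honor the design layout", {
  des <- study_design(n_participants = 6L)
  tab <- generate_dataset(des, seed = 3)
  one <- tab[tab$student_id == 1 & tab$session == 1, ]
  # 48 items split 4 per reps x spacing cell
  assign <- unique(one[, c("item_id", "reps_level", "spacing_level")])
  expect_equal(nrow(assign), 48L)
  expect_true(all(table(assign$reps_level, assign$spacing_level) == 4L))
  # each item repeated exactly reps_level times in session 1
  counts <- table(one$item_id)
  expect_equal(as.vector(counts),
               assign$reps_level[order(assign$item_id)])
  # every history starts with a study trial
  firsts <- one[!duplicated(one$item_id), ]
  expect_true(all(firsts$kind == "study"))
  # session 2: three blocked tests per item
  two <- tab[tab$student_id == 1 & tab$session == 2, ]
  expect_equal(as.vector(table(two$item_id)), rep(3L, 48))
  expect_true(all(two$kind == "test"))
  blocks <- matrix(two$item_id, ncol = 3)
  for (b in 1:3) expect_equal(sort(blocks[, b]), 1:48)
})

test_that("participants are split over retention levels as evenly as possible", {
  des <- study_design(n_participants = 132L)
  tab <- generate_dataset(des, seed = 5)
  split <- table(unique(tab[, c("student_id", "retention_s")])$retention_s)
  expect_equal(as.vector(split), c(44L, 44L, 44L))
  expect_equal(max(split) - min(split), 0L)
  # the historical uneven split is expressible through explicit counts
  des2 <- study_design(n_participants = 132L,
                       retention_counts = c(43L, 45L, 44L))
  tab2 <- generate_dataset(des2, seed = 5)
  split2 <- table(unique(tab2[, c("student_id", "retention_s")])$retention_s)
  expect_equal(as.vector(split2), c(43L, 45L, 44L))
})

test_that("realized session-1 spacing tracks the assigned targets", {
  tab <- generate_dataset(study_design(n_participants = 8L), seed = 21)
  one <- tab[tab$session == 1, ]
  one$pos <- stats::ave(seq_len(nrow(one)), one$student_id, FUN = seq_along)
  gaps <- do.call(rbind, lapply(split(one, one$student_id), function(s) {
    do.call(rbind, lapply(split(s, s$item_id), function(it) {
      if (nrow(it) < 2) return(NULL)
      data.frame(target = it$spacing_level[1], gap = diff(it$pos) - 1)
    }))
  }))
  cellmeans <- tapply(gaps$gap, gaps$target, mean)
  # per-cell mean realized spacing within the +/-1 jitter tolerance
  expect_true(all(abs(cellmeans - as.numeric(names(cellmeans))) <= 1))
})

test_that("generation is byte-identical under a fixed seed", {
  des <- study_design(n_participants = 4L)
  t1 <- generate_dataset(des, seed = 8)
  t2 <- generate_dataset(des, seed = 8)
  expect_identical(t1, t2)
  t3 <- generate_dataset(des, seed = 9)
  expect_false(identical(t1, t3))
})

test_that("a null generating model yields accuracy at the intercept baseline", {
  null <- model_params(0, 0, 0.1, 0.1, 0)
  dists <- list(student = c(mean = 0, sd = 0), item = c(mean = 0.5, sd = 0))
  tab <- generate_dataset(study_design(n_participants = 12L), null,
                          intercept_dists = dists, seed = 10)
  tests <- tab[tab$kind == "test" & tab$session == 2, ]
  p_true <- stats::plogis(0.5)
  n <- nrow(tests)
  expect_lt(abs(mean(tests$outcome == "success") - p_true),
            3 * sqrt(p_true * (1 - p_true) / n))
})

test_that("session-1 accuracy decreases with spacing at fixed repetitions", {
  # wider spacing means harder within-session retrieval when decay
  # dominates the spacing curvature: the generative spacing/difficulty
  # trade-off (with a large c the S^c term can reverse the direction, so a
  # decay-dominant parameterization is used here)
  tab <- generate_dataset(study_design(n_participants = 40L),
                          model_params(0.6, 0.2, 0.5, 0.7, 0.08),
                          seed = 33)
  tests <- tab[tab$kind == "test" & tab$session == 1 & tab$reps_level == 8, ]
  acc <- tapply(tests$outcome == "success", tests$spacing_level, mean)
  expect_gt(acc[["1"]], acc[["13"]])
})

test_that("recovery reports compute bias and relative error", {
  true <- model_params(1, 0.5, 0.2, 0.3, 0.1)
  rep0 <- parameter_recovery_report(true, true)
  expect_true(all(rep0$abs_error == 0))
  est <- model_params(1.1, 0.5, 0.2, 0.3, 0.1)
  rep1 <- parameter_recovery_report(true, est)
  expect_equal(rep1$rel_error[rep1$parameter == "beta_success"], 0.1)
  expect_equal(rep1$bias[rep1$parameter == "beta_success"], 0.1,
               tolerance = 1e-12)
})
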