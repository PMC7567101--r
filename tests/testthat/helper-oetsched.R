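# Shared fixtures and brute-force oracles used across the test files.

# A small, hand-checkable practice history: study at 0 s, a successful test
# at 60 s, a failed test at 180 s.
toy_history <- function() {
  item_history(c(0, 60, 180), c("study", "test", "test"),
               c("none", "success", "failure"))
}

# Naive recount oracle for compute_features: recomputes every feature
# directly from the raw event list with explicit loops, independent of the
# package's implementation.
naive_features <- function(history, now_s) {
  n <- if (is.null(nrow(history))) 0L else nrow(history)
  if (n == 0L) return(list(n_success = 0L, n_failure = 0L,
                           age_s = 1, mean_spacing_s = 1))
  ns <- 0L; nf <- 0L
  for (i in seq_len(n)) {
    if (history$kind[i] == "study") ns <- ns + 1L
    else if (history$outcome[i] == "success") ns <- ns + 1L
    else nf <- nf + 1L
  }
  gaps <- c()
  if (n >= 2L) for (i in 2:n) gaps <- c(gaps, history$time_s[i] - history$time_s[i - 1])
  list(n_success = ns, n_failure = nf,
       age_s = max(1, now_s - history$time_s[1]),
       mean_spacing_s = if (n >= 2L) max(1, mean(gaps)) else 1)
}

# Random but valid item history (study first, strictly increasing times).
random_history <- function(max_events = 8L) {
  n <- sample.int(max_events, 1L)
  times <- cumsum(c(stats::runif(1, 0, 10), stats::runif(n - 1, 0.5, 400)))
  kind <- c("study", sample(c("study", "test"), n - 1L, replace = TRUE,
                            prob = c(0.2, 0.8)))
  outcome <- ifelse(kind == "study", "none",
                    sample(c("success", "failure"), n, replace = TRUE))
  item_history(times, kind, outcome)
}

# Generating truth for parameter-recovery studies: every component is scaled
# to leave a detectable signal on the design's time scales (the simulation
# reference parameterization deliberately has a near-vanishing failure trace,
# which no estimator could pin down in relative terms).
recovery_truth <- function() model_params(0.5, 0.3, 0.2, 0.4, 0.3)

# Small reusable simulation fixtures (kept tiny so the default suite is
# quick; the acceptance file runs the full-size study).
tiny_population <- function(n_students = 5L, n_items = 10L, seed = 7L) {
  sample_population(n_students, n_items,
                    student_dist = c(0, 1), item_dist = c(-2, 1),
                    seed = seed)
}
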