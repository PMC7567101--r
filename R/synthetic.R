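#' Study design for synthetic trial logs
#'
#' Describes a two-session cued-recall parameterization study: session 1
#' manipulates repetitions and spacing within participant (items divided
#' equally over the reps-by-spacing cells), the retention interval before
#' session 2 is manipulated between participants, and session 2 tests every
#' item a fixed number of times in randomized blocks (an item is not
#' retested until all others have been tested).
#'
#' @param n_participants number of participants (default 132).
#' @param items_per_participant items per participant (default 48); must be
#'   divisible by the number of reps-by-spacing cells.
#' @param reps_levels repetition counts manipulated within participant
#'   (default \code{c(2, 4, 8)}; the first trial of an item is a study
#'   exposure, the rest are tests).
#' @param spacing_levels target intervening-trial counts between an item's
#'   repetitions (default \code{c(1, 4, 8, 13)}: very narrow to very wide).
#' @param retention_levels_s between-participant retention intervals in
#'   seconds (default 2 minutes, 1 day, 3 days).
#' @param retention_counts optional explicit participant counts per
#'   retention level (must sum to \code{n_participants}); by default
#'   participants are split as evenly as possible.
#' @param session2_tests_per_item blocked test rounds in session 2
#'   (default 3).
#' @return An object of class \code{"study_design"}.
#' @export
study_design <- function(n_participants = 132L,
                         items_per_participant = 48L,
                         reps_levels = c(2L, 4L, 8L),
                         spacing_levels = c(1L, 4L, 8L, 13L),
                         retention_levels_s = c(120, 86400, 259200),
                         retention_counts = NULL,
                         session2_tests_per_item = 3L) {
  n_cells <- length(reps_levels) * length(spacing_levels)
  if (items_per_participant %% n_cells != 0L)
    stop(sprintf(
      "items_per_participant (%d) must divide equally among the %d reps x spacing cells",
      items_per_participant, n_cells))
  if (!is.null(retention_counts)) {
    if (length(retention_counts) != length(retention_levels_s) ||
        sum(retention_counts) != n_participants)
      stop("retention_counts must match retention_levels_s and sum to n_participants")
  }
  structure(list(n_participants = as.integer(n_participants),
                 items_per_participant = as.integer(items_per_participant),
                 reps_levels = as.integer(reps_levels),
                 spacing_levels = as.integer(spacing_levels),
                 retention_levels_s = as.numeric(retention_levels_s),
                 retention_counts = retention_counts,
                 session2_tests_per_item = as.integer(session2_tests_per_item)),
            class = "study_design")
}

# Split n participants over k levels as evenly as possible.
even_split <- function(n, k) {
  base <- n %/% k
  counts <- rep(base, k)
  extra <- n - base * k
  if (extra > 0) counts[seq_len(extra)] <- counts[seq_len(extra)] + 1L
  counts
}

# Lay out one participant's session-1 sequence: each item repeated reps[i]
# times with target gap (spacing[i] + 1) positions between repetitions.
# Ideal positions (randomized staggering + earliest-due-date linearization)
# approximate the mixed reps-by-spacing targets; optional +/-1 jitter.
session1_sequence <- function(reps, spacing, jitter = TRUE) {
  n_items <- length(reps)
  total <- sum(reps)
  gap <- spacing + 1
  span <- (reps - 1) * gap
  start <- stats::runif(n_items) * pmax(1, total - span - 1) + 1
  gap_list <- lapply(seq_len(n_items), function(i)
    rep(gap[i], reps[i] - 1L))
  edf_sequence(gap_list, start, jitter = jitter)
}

#' Generate a synthetic trial log from known parameters
#'
#' Simulates the full two-session design of [study_design()] from known
#' correctness- and latency-model parameters, producing a trial table
#' suitable for [fit_correctness()]/[fit_latency()] parameter-recovery
#' studies.  Outcomes are Bernoulli draws from the true model; response
#' times of correct trials come from the true latency model plus truncated
#' Gaussian noise; trial and feedback durations follow the timing
#' constants, so event times are clock-accurate within and across sessions.
#'
#' @param design a [study_design()].
#' @param true_params a [model_params()] object (the generating truth).
#' @param latency a [latency_params()] object.
#' @param intercept_dists list with \code{student} and \code{item}
#'   components, each \code{c(mean, sd)} of a Gaussian (default
#'   [reference_intercept_dists()]).
#' @param timing a [timing_constants()] object.
#' @param rt_noise_sd Gaussian RT noise, seconds (default 0.3, truncated so
#'   RTs stay above 0.2 s).
#' @param seed integer seed; regeneration with the same seed is
#'   byte-identical.
#' @return A trial table data frame with columns \code{student_id},
#'   \code{item_id}, \code{time_s}, \code{kind}, \code{outcome},
#'   \code{rt_s}, plus assignment columns \code{reps_level},
#'   \code{spacing_level}, \code{retention_s}, \code{session}.
#' @export
generate_dataset <- function(design = study_design(),
                             true_params = reference_params(),
                             latency = reference_latency(),
                             intercept_dists = reference_intercept_dists(),
                             timing = timing_constants(),
                             rt_noise_sd = 0.3,
                             seed = 1L) {
  old <- .Random.seed_save(); on.exit(.Random.seed_restore(old))
  set.seed(as.integer(seed))
  n_items <- design$items_per_participant
  cells <- expand.grid(reps = design$reps_levels,
                       spacing = design$spacing_levels)
  per_cell <- n_items / nrow(cells)
  counts <- if (is.null(design$retention_counts))
    even_split(design$n_participants, length(design$retention_levels_s))
  else design$retention_counts
  retention_by_p <- rep(design$retention_levels_s, counts)

  bs <- true_params$beta_success; bf <- true_params$beta_failure
  ds <- true_params$decay_success; df_ <- true_params$decay_failure
  cc <- true_params$spacing_curvature

  # one intercept per word pair, shared by all participants (the item pool
  # is common to the whole study), and one intercept per participant
  i_int <- stats::rnorm(n_items, intercept_dists$item[1],
                        intercept_dists$item[2])
  s_ints <- stats::rnorm(design$n_participants, intercept_dists$student[1],
                         intercept_dists$student[2])

  out <- vector("list", design$n_participants)
  for (p in seq_len(design$n_participants)) {
    s_int <- s_ints[p]
    cell_of <- sample(rep(seq_len(nrow(cells)), each = per_cell))
    reps <- cells$reps[cell_of]; spacing <- cells$spacing[cell_of]
    seq1 <- session1_sequence(reps, spacing, jitter = TRUE)
    blocks <- unlist(lapply(seq_len(design$session2_tests_per_item),
                            function(b) sample.int(n_items)),
                     use.names = FALSE)
    item_seq <- c(seq1, blocks)
    session <- rep(1:2, c(length(seq1), length(blocks)))

    n_tr <- length(item_seq)
    time_s <- numeric(n_tr); kind <- character(n_tr)
    outcome <- character(n_tr); rt_s <- rep(NA_real_, n_tr)
    n_ev <- integer(n_items); n_s <- numeric(n_items); n_f <- numeric(n_items)
    first_t <- rep(NA_real_, n_items); last_t <- rep(NA_real_, n_items)
    gap_sum <- numeric(n_items)
    clock <- 0
    for (t in seq_len(n_tr)) {
      if (t > 1L && session[t] == 2L && session[t - 1L] == 1L)
        clock <- clock + retention_by_p[p]
      it <- item_seq[t]
      time_s[t] <- clock
      if (n_ev[it] == 0L) {
        kind[t] <- "study"; outcome[t] <- "none"
        dur <- timing$study_duration_s
      } else {
        kind[t] <- "test"
        age <- max(1, clock - first_t[it])
        S <- if (n_ev[it] >= 2L) max(1, gap_sum[it] / (n_ev[it] - 1L)) else 1
        act <- bs * n_s[it] * age^(-ds) * S^cc +
          bf * n_f[it] * age^(-df_) * S^cc
        pr <- logistic(act + s_int + i_int[it])
        pr <- min(max(pr, 1e-12), 1 - 1e-12)
        if (stats::runif(1) < pr) {
          outcome[t] <- "success"
          rt <- predict_rt(stats::qlogis(pr), latency) +
            stats::rnorm(1, 0, rt_noise_sd)
          rt <- min(max(rt, 0.2), timing$max_response_s)
          rt_s[t] <- rt
          dur <- rt + timing$correct_feedback_s
        } else {
          outcome[t] <- "failure"
          dur <- timing$failure_response_s + timing$failure_feedback_s
        }
      }
      if (n_ev[it] > 0L) gap_sum[it] <- gap_sum[it] + (clock - last_t[it])
      if (n_ev[it] == 0L) first_t[it] <- clock
      last_t[it] <- clock
      n_ev[it] <- n_ev[it] + 1L
      if (kind[t] == "study" || outcome[t] == "success")
        n_s[it] <- n_s[it] + 1
      if (outcome[t] == "failure") n_f[it] <- n_f[it] + 1
      clock <- clock + dur + timing$isi_s
    }
    out[[p]] <- data.frame(
      student_id = p, item_id = item_seq, time_s = time_s, kind = kind,
      outcome = outcome, rt_s = rt_s,
      reps_level = reps[item_seq], spacing_level = spacing[item_seq],
      retention_s = retention_by_p[p], session = session,
      stringsAsFactors = FALSE)
  }
  res <- do.call(rbind, out)
  attr(res, "true_intercepts") <- list(student = s_ints, item = i_int)
  res
}

#' Parameter-recovery report
#'
#' Compares fitted correctness-model parameters against the generating
#' truth, reporting signed bias and absolute relative error per parameter
#' and flagging estimates at the optimizer bounds.
#'
#' @param true the generating [model_params()].
#' @param fitted a \code{"correctness_fit"} from [fit_correctness()] (or a
#'   [model_params()]).
#' @param bounds the decay/curvature bounds used in fitting (for boundary
#'   flags).
#' @return Data frame with one row per parameter: \code{parameter},
#'   \code{true}, \code{fitted}, \code{bias}, \code{rel_error},
#'   \code{abs_error}, \code{at_boundary}.
#' @export
parameter_recovery_report <- function(true, fitted,
                                      bounds = list(decay = c(0, 1.5),
                                                    curvature = c(-1, 1))) {
  est <- if (inherits(fitted, "correctness_fit")) fitted$params else fitted
  pars <- c("beta_success", "beta_failure", "decay_success",
            "decay_failure", "spacing_curvature")
  tv <- unlist(true[pars]); fv <- unlist(est[pars])
  lo <- c(-Inf, -Inf, bounds$decay[1], bounds$decay[1], bounds$curvature[1])
  hi <- c(Inf, Inf, bounds$decay[2], bounds$decay[2], bounds$curvature[2])
  eps <- 1e-4
  data.frame(parameter = pars, true = tv, fitted = fv, bias = fv - tv,
             rel_error = ifelse(tv != 0, abs(fv - tv) / abs(tv), NA_real_),
             abs_error = abs(fv - tv),
             at_boundary = fv <= lo + eps | fv >= hi - eps,
             row.names = NULL, stringsAsFactors = FALSE)
}
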