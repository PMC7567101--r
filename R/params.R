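#' Correctness-model parameters
#'
#' Bundles the five free parameters of the two-component power-decay recall
#' model.  The linear predictor for an item with practice features
#' \eqn{(N_s, N_f, a, S)} is
#' \deqn{y = \beta_1 a^{-d_s} N_s S^c + \beta_2 a^{-d_f} N_f S^c,}
#' where \eqn{a} is seconds since first practice, \eqn{S} the mean spacing in
#' seconds between practice attempts, and \eqn{N_s, N_f} counts of prior
#' successes and failures.  The two additive components allow successes and
#' failures to contribute (and decay) differently; the spacing curvature
#' \eqn{c} is shared by both.
#'
#' @param beta_success weight of the success component (\eqn{\beta_1}).
#' @param beta_failure weight of the failure component (\eqn{\beta_2}).
#' @param decay_success power-law decay rate of the success component
#'   (\eqn{d_s}), must be non-negative.
#' @param decay_failure power-law decay rate of the failure component
#'   (\eqn{d_f}), must be non-negative.
#' @param spacing_curvature spacing-curvature exponent \eqn{c} applied to the
#'   mean spacing \eqn{S}, shared by both components.
#'
#' @return An object of class \code{"model_params"}.
#' @seealso [activation()], [predict_recall()], [reference_params()]
#' @export
#' @examples
#' model_params(1, 0.5, 0.2, 0.3, 0.1)
model_params <- function(beta_success, beta_failure,
                         decay_success, decay_failure,
                         spacing_curvature) {
  p <- list(beta_success = as.numeric(beta_success),
            beta_failure = as.numeric(beta_failure),
            decay_success = as.numeric(decay_success),
            decay_failure = as.numeric(decay_failure),
            spacing_curvature = as.numeric(spacing_curvature))
  vals <- unlist(p)
  if (length(vals) != 5L || anyNA(vals) || any(!is.finite(vals)))
    stop("all model parameters must be single finite numbers")
  if (p$decay_success < 0 || p$decay_failure < 0)
    stop("decay_success and decay_failure must be >= 0")
  structure(p, class = "model_params")
}

#' @export
print.model_params <- function(x, ...) {
  cat("Correctness-model parameters:\n")
  cat(sprintf("  beta_success (b1)      = %.4f\n", x$beta_success))
  cat(sprintf("  beta_failure (b2)      = %.4f\n", x$beta_failure))
  cat(sprintf("  decay_success (d_s)    = %.4f\n", x$decay_success))
  cat(sprintf("  decay_failure (d_f)    = %.4f\n", x$decay_failure))
  cat(sprintf("  spacing_curvature (c)  = %.4f\n", x$spacing_curvature))
  invisible(x)
}

#' Student and item intercepts
#'
#' Additive log-odds offsets entering the logistic link together with the
#' practice-history activation: the student intercept captures learner
#' ability, the item intercept captures item easiness.
#'
#' @param student_intercept log-odds offset for the learner.
#' @param item_intercept log-odds offset for the item.
#' @return An object of class \code{"intercept_set"}.
#' @export
intercept_set <- function(student_intercept = 0, item_intercept = 0) {
  s <- as.numeric(student_intercept); i <- as.numeric(item_intercept)
  if (length(s) != 1L || length(i) != 1L || !is.finite(s) || !is.finite(i))
    stop("intercepts must be single finite numbers")
  structure(list(student_intercept = s, item_intercept = i),
            class = "intercept_set")
}

#' Latency-model parameters
#'
#' The correct-response latency model maps the correctness model's log-odds
#' prediction \eqn{m} to an expected response time
#' \deqn{RT = c\, e^{-m} + f_c,} so well-known items (high log-odds) are
#' answered quickly, approaching the floor \eqn{f_c}.
#'
#' @param rt_scale scale \eqn{c} of the exponential term, seconds, > 0.
#' @param rt_floor asymptotic minimum response time \eqn{f_c}, seconds, > 0.
#' @return An object of class \code{"latency_params"}.
#' @seealso [predict_rt()], [fit_latency()]
#' @export
latency_params <- function(rt_scale, rt_floor) {
  s <- as.numeric(rt_scale); f <- as.numeric(rt_floor)
  if (length(s) != 1L || length(f) != 1L || !is.finite(s) || !is.finite(f) ||
      s <= 0 || f <= 0)
    stop("rt_scale and rt_floor must be single finite positive numbers")
  structure(list(rt_scale = s, rt_floor = f), class = "latency_params")
}

#' Trial-timing constants
#'
#' Fixed trial-duration components used by the simulator, in seconds.  The
#' defaults reproduce a typical cued-recall paradigm: 7 s initial study
#' presentation, a 7 s response window, 0.5 s confirmation after correct
#' answers, 4 s corrective feedback after failures (4.98 s median failure
#' response + 4 s feedback = 8.98 s total), a 1 s inter-stimulus interval,
#' and an 11 s fixed test-trial duration (7 s recall + 4 s feedback) for
#' fixed-duration conditions.
#'
#' @param study_duration_s duration of a study (presentation) trial.
#' @param max_response_s response window; correct-response latency is capped
#'   here.
#' @param correct_feedback_s confirmation message time after a success.
#' @param failure_response_s time spent responding on a failed trial.
#' @param failure_feedback_s corrective-feedback time after a failure.
#' @param isi_s inter-stimulus interval between trials.
#' @param fixed_test_duration_s test-trial duration in fixed-duration mode.
#' @return An object of class \code{"timing_constants"}.
#' @export
timing_constants <- function(study_duration_s = 7,
                             max_response_s = 7,
                             correct_feedback_s = 0.5,
                             failure_response_s = 4.98,
                             failure_feedback_s = 4.0,
                             isi_s = 1.0,
                             fixed_test_duration_s = 11) {
  t <- list(study_duration_s = as.numeric(study_duration_s),
            max_response_s = as.numeric(max_response_s),
            correct_feedback_s = as.numeric(correct_feedback_s),
            failure_response_s = as.numeric(failure_response_s),
            failure_feedback_s = as.numeric(failure_feedback_s),
            isi_s = as.numeric(isi_s),
            fixed_test_duration_s = as.numeric(fixed_test_duration_s))
  vals <- unlist(t)
  if (anyNA(vals) || any(!is.finite(vals)) || any(vals < 0))
    stop("all timing constants must be finite and >= 0")
  structure(t, class = "timing_constants")
}

#' Reference parameterization for simulation studies
#'
#' The fitted parameter values behind published simulation studies of this
#' kind are generally not printed, so the package ships its own documented
#' reference parameterization for the correctness and latency models and the
#' intercept distributions.  It is chosen (and documented in the methods
#' vignette) to exhibit the qualitative phenomena the models are built
#' around: forgetting over multi-day retention, a positive spacing benefit
#' (\eqn{c > 0}), successes contributing more and decaying more slowly than
#' failures (\eqn{\beta_1 > \beta_2 > 0}, \eqn{d_s < d_f}), and faster
#' correct responses for better-known items.  It is emphatically not an
#' estimate from any human dataset.
#'
#' @return \code{reference_params()}: a [model_params()] object.
#' @export
reference_params <- function() {
  model_params(beta_success = 0.25, beta_failure = 0.10,
               decay_success = 0.03, decay_failure = 0.45,
               spacing_curvature = 0.35)
}

#' @rdname reference_params
#' @return \code{reference_latency()}: a [latency_params()] object.
#' @export
reference_latency <- function() {
  latency_params(rt_scale = 3.0, rt_floor = 1.2)
}
# (floor 1.2 s: fast correct responses for well-known items; scale 3 s puts
# a 50%-known item near 4 s, inside the 7 s response window)

#' @rdname reference_params
#' @return \code{reference_intercept_dists()}: a list with Gaussian
#'   \code{student} and \code{item} components, each \code{c(mean, sd)}.
#'   The item mean is well below zero: a never-studied foreign-vocabulary
#'   pair is almost never recallable, so its baseline log-odds must be
#'   strongly negative.
#' @export
reference_intercept_dists <- function() {
  list(student = c(mean = 0, sd = 1), item = c(mean = -2.5, sd = 1.2))
}
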