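#' Build an item practice history
#'
#' An item history is the ordered record of everything one learner did with
#' one item: an initial study exposure followed by test attempts.  It is
#' stored as a data frame with columns \code{time_s} (seconds from the
#' session-clock origin, strictly increasing), \code{kind} (\code{"study"}
#' or \code{"test"}), \code{outcome} (\code{"none"} for study trials,
#' \code{"success"}/\code{"failure"} for tests) and \code{duration_s}.
#'
#' @param time_s numeric vector of event onset times, strictly increasing.
#' @param kind character vector, \code{"study"} or \code{"test"}.
#' @param outcome character vector; must be \code{"none"} exactly where
#'   \code{kind == "study"} and \code{"success"}/\code{"failure"} where
#'   \code{kind == "test"}.
#' @param duration_s positive event durations (seconds); defaults to 1.
#' @return A data frame of class \code{"item_history"}.
#' @export
#' @examples
#' h <- item_history(c(0, 60, 180), c("study", "test", "test"),
#'                   c("none", "success", "failure"))
#' compute_features(h, now_s = 300)
item_history <- function(time_s = numeric(), kind = character(),
                         outcome = character(),
                         duration_s = rep(1, length(time_s))) {
  n <- length(time_s)
  if (length(kind) != n || length(outcome) != n || length(duration_s) != n)
    stop("time_s, kind, outcome, duration_s must have equal length")
  h <- data.frame(time_s = as.numeric(time_s), kind = as.character(kind),
                  outcome = as.character(outcome),
                  duration_s = as.numeric(duration_s),
                  stringsAsFactors = FALSE)
  validate_item_history(h)
  class(h) <- c("item_history", "data.frame")
  h
}

validate_item_history <- function(h) {
  if (nrow(h) == 0L) return(invisible(h))
  if (any(!h$kind %in% c("study", "test")))
    stop("kind must be 'study' or 'test'")
  if (any(h$kind == "study" & h$outcome != "none"))
    stop("study events must have outcome 'none'")
  if (any(h$kind == "test" & !h$outcome %in% c("success", "failure")))
    stop("test events must have outcome 'success' or 'failure'")
  if (any(diff(h$time_s) <= 0))
    stop("event times must be strictly increasing")
  if (any(h$duration_s <= 0))
    stop("durations must be > 0")
  if (h$kind[1L] != "study")
    stop("the first event of a history must be a study trial")
  invisible(h)
}

#' Practice-history features
#'
#' Reduces an item history to the four features the correctness model needs:
#' success count \eqn{N_s} (study exposures count as feedback-equivalent
#' successes, so the count starts accumulating at the initial study trial),
#' failure count \eqn{N_f} (failed test attempts), age \eqn{a} (seconds
#' since first practice) and mean spacing \eqn{S} (mean seconds between
#' consecutive practice events).  Age and spacing are floored at 1 s so the
#' power terms \eqn{a^{-d}} and \eqn{S^c} stay finite at or near zero
#' elapsed time; 1 s is below any realizable trial gap.  With fewer than
#' two events the mean spacing is 1, and an empty history yields
#' \code{(0, 0, 1, 1)}.
#'
#' @param history an [item_history()] (or any data frame with the same
#'   columns).
#' @param now_s evaluation time in seconds; must not precede the last event.
#' @return An object of class \code{"feature_vector"}: a list with
#'   \code{n_success}, \code{n_failure}, \code{age_s}, \code{mean_spacing_s}.
#' @seealso [activation()], [predict_recall()]
#' @export
compute_features <- function(history, now_s) {
  stopifnot(is.numeric(now_s), length(now_s) == 1L, is.finite(now_s))
  n <- nrow(history)
  if (is.null(n) || n == 0L) {
    return(structure(list(n_success = 0L, n_failure = 0L,
                          age_s = 1, mean_spacing_s = 1),
                     class = "feature_vector"))
  }
  if (now_s < history$time_s[n])
    stop("clock violation: now_s precedes the last recorded event")
  ns <- sum(history$kind == "study" |
              (history$kind == "test" & history$outcome == "success"))
  nf <- sum(history$kind == "test" & history$outcome == "failure")
  age <- max(1, now_s - history$time_s[1L])
  spacing <- if (n >= 2L) max(1, mean(diff(history$time_s))) else 1
  structure(list(n_success = as.integer(ns), n_failure = as.integer(nf),
                 age_s = age, mean_spacing_s = spacing),
            class = "feature_vector")
}

#' @export
print.feature_vector <- function(x, ...) {
  cat(sprintf("Practice features: N_s=%d N_f=%d age=%.1fs mean spacing=%.1fs\n",
              x$n_success, x$n_failure, x$age_s, x$mean_spacing_s))
  invisible(x)
}

#' Memory activation from practice features
#'
#' Evaluates the two-component power-decay linear predictor
#' \eqn{\beta_1 a^{-d_s} N_s S^c + \beta_2 a^{-d_f} N_f S^c}.  With both
#' counts zero the activation is exactly 0 regardless of the parameters.
#'
#' @param features a \code{"feature_vector"} from [compute_features()], or a
#'   list with the same fields (fields may be vectors of equal length).
#' @param params a [model_params()] object.
#' @return Numeric activation value(s) on the log-odds scale.
#' @export
activation <- function(features, params) {
  a <- features$age_s
  S <- features$mean_spacing_s
  sc <- S^params$spacing_curvature
  params$beta_success * a^(-params$decay_success) * features$n_success * sc +
    params$beta_failure * a^(-params$decay_failure) * features$n_failure * sc
}

# logistic, safe for |x| up to the largest representable exponent
logistic <- function(x) stats::plogis(pmin(pmax(x, -745), 745))

#' Predicted recall probability
#'
#' Logistic prediction of recall: the practice-history activation plus the
#' student and item log-odds intercepts, passed through the logistic link.
#' The result lies strictly inside (0, 1) and is numerically safe for
#' log-odds magnitudes up to 700.
#'
#' @inheritParams activation
#' @param intercepts an [intercept_set()].
#' @return Recall probability in (0, 1).
#' @export
#' @examples
#' f <- compute_features(item_history(), now_s = 0)
#' predict_recall(f, model_params(1, .5, .2, .3, .1), intercept_set(0, 0))
predict_recall <- function(features, params, intercepts) {
  eta <- activation(features, params) +
    intercepts$student_intercept + intercepts$item_intercept
  p <- logistic(eta)
  pmin(pmax(p, .Machine$double.xmin), 1 - .Machine$double.neg.eps)
}
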