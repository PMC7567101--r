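#' Gain/cost terms of the practice-efficiency calculus
#'
#' Practice utility weighs what a trial buys (learning gain) against what it
#' costs (time).  Gains and costs can differ sharply between correct and
#' incorrect trials: successes are usually fast while failures incur lengthy
#' corrective feedback.
#'
#' @param gain_correct learning gain of a successful trial (utility units).
#' @param cost_correct_s time cost of a successful trial, seconds, > 0.
#' @param gain_failure learning gain of a failed trial.
#' @param cost_failure_s time cost of a failed trial, seconds, > 0.
#' @return An object of class \code{"efficiency_terms"}.
#' @export
efficiency_terms <- function(gain_correct, cost_correct_s,
                             gain_failure, cost_failure_s) {
  e <- list(gain_correct = as.numeric(gain_correct),
            cost_correct_s = as.numeric(cost_correct_s),
            gain_failure = as.numeric(gain_failure),
            cost_failure_s = as.numeric(cost_failure_s))
  vals <- unlist(e)
  if (anyNA(vals) || any(!is.finite(vals)))
    stop("efficiency terms must be finite")
  if (e$cost_correct_s <= 0 || e$cost_failure_s <= 0)
    stop("costs must be strictly positive")
  structure(e, class = "efficiency_terms")
}

#' Expected utility (efficiency) of a practice attempt
#'
#' The microeconomic efficiency of attempting an item whose success
#' probability is \eqn{p}:
#' \deqn{U = p\,\frac{g_{correct}}{k_{correct}} +
#'       (1-p)\,\frac{g_{incorrect}}{k_{incorrect}},}
#' a gain-per-second expectation over the two trial outcomes.  This is a
#' diagnostic/reporting quantity; the live selection rule used by the
#' adaptive scheduler is the probability-threshold policy
#' ([next_item_oet()]), which operationalizes the same efficiency logic via
#' a simulated threshold sweep.
#'
#' @param p probability of a correct response, in \[0, 1\] (vectorized).
#' @param terms an [efficiency_terms()] object.
#' @return Expected utility per second.
#' @export
#' @examples
#' expected_utility(0.68, efficiency_terms(0.1, 3.1, 0.1, 8.98))
expected_utility <- function(p, terms) {
  stopifnot(is.numeric(p))
  if (any(!is.finite(p)) || any(p < 0) || any(p > 1))
    stop("p must lie in [0, 1]")
  p * (terms$gain_correct / terms$cost_correct_s) +
    (1 - p) * (terms$gain_failure / terms$cost_failure_s)
}

#' Learning gain of a hypothetical practice attempt
#'
#' The change in predicted recall at a later evaluation time (typically the
#' final test) caused by appending one hypothetical test attempt, with the
#' given outcome, to an item's history now.  \code{"probability_gain"}
#' returns the change on the probability scale, \code{"logit_gain"} on the
#' log-odds scale; the two always share sign.
#'
#' @param history an [item_history()].
#' @param hypothetical_outcome \code{"success"} or \code{"failure"}.
#' @param now_s time of the hypothetical attempt (seconds).
#' @param eval_time_s evaluation time, must be strictly after \code{now_s}.
#' @param params a [model_params()] object.
#' @param intercepts an [intercept_set()].
#' @param metric \code{"probability_gain"} or \code{"logit_gain"}.
#' @return Signed gain (probability or log-odds units).
#' @export
trial_gain <- function(history, hypothetical_outcome, now_s, eval_time_s,
                       params, intercepts,
                       metric = c("probability_gain", "logit_gain")) {
  metric <- match.arg(metric)
  if (!hypothetical_outcome %in% c("success", "failure"))
    stop("hypothetical_outcome must be 'success' or 'failure'")
  if (eval_time_s <= now_s)
    stop("eval_time_s must be strictly after now_s")
  n <- if (is.null(nrow(history))) 0L else nrow(history)
  if (n > 0L && now_s < history$time_s[n])
    stop("clock violation: now_s precedes the last recorded event")
  if (n == 0L) {
    # an unpracticed item gets a study exposure, not a test
    after <- item_history(now_s, "study", "none")
  } else {
    after <- rbind(as.data.frame(history),
                   data.frame(time_s = now_s, kind = "test",
                              outcome = hypothetical_outcome, duration_s = 1,
                              stringsAsFactors = FALSE))
    class(after) <- c("item_history", "data.frame")
  }
  p0 <- predict_recall(compute_features(history, eval_time_s), params, intercepts)
  p1 <- predict_recall(compute_features(after, eval_time_s), params, intercepts)
  switch(metric,
         probability_gain = p1 - p0,
         logit_gain = stats::qlogis(p1) - stats::qlogis(p0))
}
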