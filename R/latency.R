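#' Predicted correct-response latency
#'
#' Maps the correctness model's log-odds prediction to an expected response
#' time via \eqn{RT = c\,e^{-m} + f_c}: the better known an item, the faster
#' the correct response, approaching the floor \code{rt_floor}.  The
#' exponent is capped so extreme negative log-odds cannot overflow.
#'
#' @param log_odds numeric vector of correctness-model log-odds.
#' @param params a [latency_params()] object.
#' @return Predicted response time(s) in seconds.
#' @export
#' @examples
#' predict_rt(0, latency_params(3, 1.5))   # 4.5 s
#' predict_rt(1, latency_params(3, 1.5))   # 3 * exp(-1) + 1.5
predict_rt <- function(log_odds, params) {
  stopifnot(is.numeric(log_odds), all(is.finite(log_odds)))
  params$rt_scale * exp(-pmin(log_odds, 700)) + params$rt_floor
}

#' Duration of a simulated trial
#'
#' Assigns the wall-clock duration of one trial (excluding the ISI).  Study
#' trials always take \code{study_duration_s}.  In \code{"fixed"} mode every
#' test trial takes \code{fixed_test_duration_s} (the convention of
#' fixed-duration spacing designs).  In \code{"latency_model"} mode a
#' successful test takes the predicted latency, capped at the response
#' window, plus the correct-feedback time, while a failed test takes the
#' fixed failure response time plus corrective feedback (8.98 s with the
#' default constants).
#'
#' @param kind \code{"study"} or \code{"test"}.
#' @param outcome \code{"none"} for study, \code{"success"}/\code{"failure"}
#'   for tests.
#' @param log_odds correctness-model log-odds for the trial (used only for
#'   successful tests in latency mode).
#' @param mode \code{"fixed"} or \code{"latency_model"}.
#' @param timing a [timing_constants()] object.
#' @param params a [latency_params()] object.
#' @return Trial duration in seconds.
#' @export
trial_duration <- function(kind, outcome, log_odds = 0,
                           mode = c("latency_model", "fixed"),
                           timing = timing_constants(),
                           params = reference_latency()) {
  mode <- match.arg(mode)
  if (kind == "study") {
    if (outcome != "none") stop("study trials must have outcome 'none'")
    return(timing$study_duration_s)
  }
  if (kind != "test") stop("kind must be 'study' or 'test'")
  if (!outcome %in% c("success", "failure"))
    stop("test trials must have outcome 'success' or 'failure'")
  if (mode == "fixed") return(timing$fixed_test_duration_s)
  if (outcome == "success") {
    min(predict_rt(log_odds, params), timing$max_response_s) +
      timing$correct_feedback_s
  } else {
    timing$failure_response_s + timing$failure_feedback_s
  }
}
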