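#' Per-test-trial model features from a trial table
#'
#' Expands a trial-level log into one row per test trial with the practice
#' features (success count, failure count, age, mean spacing) computed from
#' that student-item pair's history strictly before the trial.  Study
#' exposures count toward the success count, exactly as in
#' [compute_features()].
#'
#' @param table a trial table: data frame with columns \code{student_id},
#'   \code{item_id}, \code{time_s}, \code{kind} (\code{"study"}/\code{"test"}),
#'   \code{outcome} (\code{"none"}/\code{"success"}/\code{"failure"}) and
#'   optionally \code{rt_s}.
#' @return Data frame of test rows with columns \code{student_id},
#'   \code{item_id}, \code{time_s}, \code{y} (1 = success), \code{n_success},
#'   \code{n_failure}, \code{age_s}, \code{mean_spacing_s}, \code{rt_s}.
#' @export
trial_features <- function(table) {
  required <- c("student_id", "item_id", "time_s", "kind", "outcome")
  if (!all(required %in% names(table)))
    stop("trial table must have columns ", paste(required, collapse = ", "))
  if (nrow(table) == 0L) stop("empty trial table")
  tab <- table[order(table$student_id, table$item_id, table$time_s), ]
  g <- interaction(tab$student_id, tab$item_id, drop = TRUE)
  idx <- stats::ave(seq_len(nrow(tab)), g, FUN = seq_along)
  is_s <- as.numeric(tab$kind == "study" |
                       (tab$kind == "test" & tab$outcome == "success"))
  is_f <- as.numeric(tab$kind == "test" & tab$outcome == "failure")
  prior_ns <- stats::ave(is_s, g, FUN = cumsum) - is_s
  prior_nf <- stats::ave(is_f, g, FUN = cumsum) - is_f
  first_t <- stats::ave(tab$time_s, g, FUN = function(x) x[1L])
  prev_t <- stats::ave(tab$time_s, g,
                       FUN = function(x) c(NA_real_, x[-length(x)]))
  n_prior <- idx - 1L
  age <- pmax(1, tab$time_s - first_t)
  spacing <- ifelse(n_prior >= 2L,
                    pmax(1, (prev_t - first_t) / pmax(1L, n_prior - 1L)), 1)
  keep <- tab$kind == "test"
  data.frame(student_id = tab$student_id[keep], item_id = tab$item_id[keep],
             time_s = tab$time_s[keep],
             y = as.integer(tab$outcome[keep] == "success"),
             n_success = prior_ns[keep], n_failure = prior_nf[keep],
             age_s = age[keep], mean_spacing_s = spacing[keep],
             rt_s = if ("rt_s" %in% names(tab)) tab$rt_s[keep] else NA_real_,
             stringsAsFactors = FALSE)
}

# Ridge-penalized logistic IRLS on a sparse design.  The first `n_free`
# columns (the two component slopes) are unpenalized; all intercept columns
# get an L2 penalty `ridge`.  Returns coefficients, penalized deviance and
# the unpenalized log-likelihood.
penalized_logistic <- function(X, y, n_free, ridge, w_init = NULL,
                               maxit = 50L, tol = 1e-9) {
  p <- ncol(X)
  pen <- c(rep(0, n_free), rep(ridge, p - n_free))
  # a component with no supporting observations (all-zero column) would make
  # the Hessian exactly singular; a negligible floor keeps it solvable and
  # pins the unidentifiable coefficient at 0
  zero_col <- Matrix::colSums(abs(X)) == 0
  pen[zero_col] <- pmax(pen[zero_col], 1e-6)
  w <- if (is.null(w_init)) rep(0, p) else w_init
  obj_old <- Inf; converged <- FALSE
  for (it in seq_len(maxit)) {
    eta <- as.numeric(X %*% w)
    mu <- logistic(eta)
    mu <- pmin(pmax(mu, 1e-12), 1 - 1e-12)
    ll <- sum(y * log(mu) + (1 - y) * log(1 - mu))
    obj <- -ll + 0.5 * sum(pen * w^2)
    if (abs(obj_old - obj) < tol * (abs(obj) + 1)) { converged <- TRUE; break }
    obj_old <- obj
    wt <- mu * (1 - mu)
    H <- as.matrix(Matrix::crossprod(X * sqrt(wt))) + diag(pen, p)
    gr <- as.numeric(Matrix::crossprod(X, y - mu)) - pen * w
    step <- solve(H, gr)
    # halving line search on the penalized objective
    lambda <- 1
    repeat {
      w_new <- w + lambda * step
      eta_n <- as.numeric(X %*% w_new)
      mu_n <- pmin(pmax(logistic(eta_n), 1e-12), 1 - 1e-12)
      obj_n <- -sum(y * log(mu_n) + (1 - y) * log(1 - mu_n)) +
        0.5 * sum(pen * w_new^2)
      if (obj_n <= obj + 1e-10 || lambda < 1e-6) break
      lambda <- lambda / 2
    }
    w <- w_new
  }
  eta <- as.numeric(X %*% w)
  mu <- pmin(pmax(logistic(eta), 1e-12), 1 - 1e-12)
  ll <- sum(y * log(mu) + (1 - y) * log(1 - mu))
  list(coef = w, log_lik = ll,
       pen_obj = -ll + 0.5 * sum(pen * w^2),
       fitted = mu, converged = converged, iterations = it)
}

#' Fit the correctness model to a trial table
#'
#' Maximum-likelihood estimation of the two-component power-decay logistic
#' recall model with student and item intercepts.  The estimation is
#' nested: for fixed decay/curvature parameters \eqn{(d_s, d_f, c)} the
#' model is linear in \eqn{(\beta_1, \beta_2,} intercepts\eqn{)} and solved
#' by a ridge-penalized iteratively reweighted least squares logistic
#' solver (the small ridge, default 1e-2, stabilizes sparse
#' student/item cells); the outer nonlinear triple is optimized
#' derivative-free (Nelder-Mead on a box-transformed scale) within bounds.
#' Study trials enter only through the features, not as Bernoulli
#' observations.
#'
#' @param table a trial table (see [trial_features()]).
#' @param init a [model_params()] with the starting values; the decays and
#'   curvature must start inside the bounds.
#' @param options list of fitting options: \code{ridge} (default 1e-2),
#'   \code{include_participant_intercepts} (default \code{TRUE}; set
#'   \code{FALSE} to refit with item intercepts only, the deployment path
#'   when scheduling for participants never seen before), \code{bounds}
#'   (list with \code{decay = c(lo, hi)} default \code{c(0, 1.5)} and
#'   \code{curvature = c(lo, hi)} default \code{c(-1, 1)}), \code{maxit}
#'   outer iterations (default 400), \code{reltol} (default 1e-7).
#' @return An object of class \code{"correctness_fit"}: the fitted
#'   [model_params()], intercept vectors and their moments, log-likelihood,
#'   null log-likelihood, McFadden pseudo-R2, training AUC, and convergence
#'   diagnostics (including identifiability flags when a component has no
#'   supporting observations).
#' @seealso [fit_latency()], [auc()], [parameter_recovery_report()]
#' @export
fit_correctness <- function(table, init = reference_params(),
                            options = list()) {
  opt <- utils::modifyList(
    list(ridge = 1e-2, include_participant_intercepts = TRUE,
         bounds = list(decay = c(0, 1.5), curvature = c(-1, 1)),
         maxit = 400L, reltol = 1e-7),
    options)
  feats <- trial_features(table)
  if (nrow(feats) == 0L) stop("no test trials to fit")
  y <- feats$y
  if (init$decay_success < opt$bounds$decay[1] ||
      init$decay_success > opt$bounds$decay[2] ||
      init$decay_failure < opt$bounds$decay[1] ||
      init$decay_failure > opt$bounds$decay[2])
    stop("initial decays must lie inside the bounds")

  students <- sort(unique(feats$student_id))
  items <- sort(unique(feats$item_id))
  si <- match(feats$student_id, students)
  ii <- match(feats$item_id, items)
  n <- nrow(feats)
  with_students <- isTRUE(opt$include_participant_intercepts)
  n_s <- if (with_students) length(students) else 0L
  n_i <- length(items)
  # fixed indicator block of the design
  rows <- c(if (with_students) seq_len(n), seq_len(n))
  cols <- c(if (with_students) 2L + si, 2L + n_s + ii)
  Z <- Matrix::sparseMatrix(i = rows, j = cols - 2L, x = 1,
                            dims = c(n, n_s + n_i))

  log_a <- log(feats$age_s); log_S <- log(feats$mean_spacing_s)
  make_X <- function(theta) {
    sc <- exp(theta[3] * log_S)
    x1 <- feats$n_success * exp(-theta[1] * log_a) * sc
    x2 <- feats$n_failure * exp(-theta[2] * log_a) * sc
    Matrix::cbind2(Matrix::Matrix(cbind(x1, x2), sparse = TRUE), Z)
  }

  lo <- c(opt$bounds$decay[1], opt$bounds$decay[1], opt$bounds$curvature[1])
  hi <- c(opt$bounds$decay[2], opt$bounds$decay[2], opt$bounds$curvature[2])
  to_z <- function(theta) stats::qlogis(pmin(pmax((theta - lo) / (hi - lo),
                                                  1e-8), 1 - 1e-8))
  from_z <- function(z) lo + (hi - lo) * logistic(z)

  warm <- new.env(parent = emptyenv()); warm$w <- NULL
  n_eval <- 0L
  objective <- function(z) {
    theta <- from_z(z)
    fit <- penalized_logistic(make_X(theta), y, n_free = 2L,
                              ridge = opt$ridge, w_init = warm$w)
    warm$w <- fit$coef
    n_eval <<- n_eval + 1L
    fit$pen_obj
  }
  z0 <- to_z(c(init$decay_success, init$decay_failure,
               init$spacing_curvature))
  om <- stats::optim(z0, objective, method = "Nelder-Mead",
                     control = list(maxit = opt$maxit, reltol = opt$reltol))
  theta <- from_z(om$par)
  inner <- penalized_logistic(make_X(theta), y, n_free = 2L,
                              ridge = opt$ridge, w_init = warm$w)
  coefs <- inner$coef
  params <- model_params(coefs[1], coefs[2], theta[1], theta[2], theta[3])
  student_int <- if (with_students)
    stats::setNames(coefs[2L + seq_len(n_s)], students) else NULL
  item_int <- stats::setNames(coefs[2L + n_s + seq_len(n_i)], items)
  # only the sum of the two intercept blocks is identified; center the
  # student block at 0 and carry the level in the item block, so the
  # reported moments are directly usable as sampling distributions
  if (with_students) {
    lvl <- mean(student_int)
    student_int <- student_int - lvl
    item_int <- item_int + lvl
  }

  p_null <- min(max(mean(y), 1e-12), 1 - 1e-12)
  ll_null <- sum(y * log(p_null) + (1 - y) * log(1 - p_null))
  ll <- inner$log_lik
  diag <- list(
    outer_converged = om$convergence == 0L,
    inner_converged = inner$converged,
    outer_evals = n_eval,
    beta_success_identifiable = sum(feats$n_success > 0) > 0,
    beta_failure_identifiable = sum(feats$n_failure > 0) > 0,
    message = if (om$convergence == 0L) "converged" else
      sprintf("outer optimizer code %d", om$convergence))
  if (!diag$beta_failure_identifiable)
    diag$message <- paste(diag$message,
                          "; beta_failure unidentifiable (no failure exposure)")
  structure(list(
    params = params,
    student_intercepts = student_int,
    item_intercepts = item_int,
    intercept_moments = list(
      student = if (with_students)
        c(mean = mean(student_int), sd = stats::sd(student_int)) else NULL,
      item = c(mean = mean(item_int), sd = stats::sd(item_int))),
    ridge = opt$ridge,
    include_participant_intercepts = with_students,
    log_lik = ll, null_log_lik = ll_null,
    mcfadden_r2 = 1 - ll / ll_null,
    auc = if (length(unique(y)) == 2L) auc(inner$fitted, y) else NA_real_,
    fitted_p = inner$fitted, features = feats,
    convergence = diag), class = "correctness_fit")
}

#' @export
print.correctness_fit <- function(x, ...) {
  cat("Correctness-model fit\n")
  print(x$params)
  cat(sprintf("  log-lik %.1f (null %.1f), McFadden R2 = %.3f, AUC = %.3f\n",
              x$log_lik, x$null_log_lik, x$mcfadden_r2, x$auc))
  cat(sprintf("  intercepts: %s students, %d items (ridge %.3g)\n",
              ifelse(x$include_participant_intercepts,
                     length(x$student_intercepts), "no"),
              length(x$item_intercepts), x$ridge))
  cat(sprintf("  %s\n", x$convergence$message))
  invisible(x)
}

#' Fit the latency model to correct-trial response times
#'
#' Least-squares (Gaussian maximum-likelihood) fit of
#' \eqn{RT = c\,e^{-m} + f_c} to the response times of correct test trials,
#' with positivity constraints on both parameters, via
#' \code{minpack.lm::nlsLM}.  A log-normal noise option fits the same mean
#' function on the log scale.
#'
#' @param rt_s response times (seconds) of correct test trials.
#' @param log_odds the corresponding correctness-model log-odds predictions.
#' @param init a [latency_params()] starting point.
#' @param noise \code{"gaussian"} (default) or \code{"lognormal"}.
#' @return A list of class \code{"latency_fit"} with \code{params} (a
#'   [latency_params()]), \code{sigma}, \code{converged} and \code{n}.
#' @export
fit_latency <- function(rt_s, log_odds, init = latency_params(3, 1.5),
                        noise = c("gaussian", "lognormal")) {
  noise <- match.arg(noise)
  keep <- is.finite(rt_s) & is.finite(log_odds)
  rt_s <- rt_s[keep]; log_odds <- log_odds[keep]
  if (length(rt_s) < 2L) stop("need at least 2 correct trials with RTs")
  if (stats::sd(log_odds) == 0)
    stop("degenerate design: all log-odds equal, rt_scale not identifiable")
  z <- exp(-pmin(log_odds, 700))
  df <- data.frame(rt = rt_s, z = z)
  if (max(z) < 1e-6 || stats::sd(z) < 1e-10 * mean(z)) {
    # the exponential term is numerically flat (e.g. uniformly huge
    # log-odds): the floor absorbs the mean and the scale sits at its bound
    fl <- max(mean(rt_s) - init$rt_scale * mean(z), 1e-8)
    return(structure(list(params = latency_params(1e-8, fl),
                          sigma = stats::sd(rt_s), converged = TRUE,
                          boundary = TRUE, n = length(rt_s), noise = noise),
                     class = "latency_fit"))
  }
  fml <- if (noise == "gaussian") rt ~ s * z + f else log(rt) ~ log(s * z + f)
  fit <- minpack.lm::nlsLM(fml, data = df,
                           start = list(s = init$rt_scale, f = init$rt_floor),
                           lower = c(1e-8, 1e-8),
                           control = minpack.lm::nls.lm.control(maxiter = 200))
  cf <- stats::coef(fit)
  structure(list(params = latency_params(max(cf[["s"]], 1e-8),
                                         max(cf[["f"]], 1e-8)),
                 sigma = stats::sigma(fit),
                 converged = fit$convInfo$isConv,
                 boundary = cf[["s"]] <= 1e-6 || cf[["f"]] <= 1e-6,
                 n = length(rt_s), noise = noise),
            class = "latency_fit")
}

#' Area under the ROC curve
#'
#' Rank-based (Mann-Whitney) AUC: the probability that a randomly chosen
#' success receives a higher prediction than a randomly chosen failure,
#' with ties counted one half.
#'
#' @param predictions numeric predictions (any monotone score).
#' @param outcomes binary outcomes (0/1 or logical).
#' @return AUC in \[0, 1\].
#' @export
#' @examples
#' auc(c(0.9, 0.8, 0.3, 0.2), c(1, 0, 1, 0))  # 0.75
auc <- function(predictions, outcomes) {
  outcomes <- as.integer(outcomes)
  if (length(predictions) != length(outcomes))
    stop("predictions and outcomes must have equal length")
  n1 <- sum(outcomes == 1L); n0 <- sum(outcomes == 0L)
  if (n1 == 0L || n0 == 0L)
    stop("both outcome classes must be present")
  r <- rank(predictions)
  (sum(r[outcomes == 1L]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}
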