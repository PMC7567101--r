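#' Practice-schedule specification
#'
#' Describes one scheduling policy.  Conventional kinds (\code{"massed"},
#' \code{"uniform"}, \code{"expanding"}, \code{"contracting"},
#' \code{"blocked_s15"}) produce a fixed item sequence up front via
#' [build_fixed_schedule()]; \code{"drop1"} and \code{"oet"} select the next
#' item trial by trial.
#'
#' @param kind one of \code{"massed"}, \code{"uniform"}, \code{"expanding"},
#'   \code{"contracting"}, \code{"blocked_s15"}, \code{"drop1"},
#'   \code{"oet"}.
#' @param nominal_spacing_trials target number of intervening trials between
#'   repetitions of an item (0 for massed; conventional studies commonly use
#'   0, 15 or 30).
#' @param reps_per_item repetitions per item for fixed schedules.
#' @param jitter logical; shift each planned repetition position by
#'   -1/0/+1 uniformly, resolving conflicts by stable reordering.
#' @param threshold recall-probability threshold, required iff
#'   \code{kind == "oet"}.
#' @return An object of class \code{"schedule_spec"}.
#' @export
schedule_spec <- function(kind, nominal_spacing_trials = 0L,
                          reps_per_item = 4L, jitter = FALSE,
                          threshold = NULL) {
  kinds <- c("massed", "uniform", "expanding", "contracting",
             "blocked_s15", "drop1", "oet")
  kind <- match.arg(kind, kinds)
  if (kind == "oet") {
    if (is.null(threshold) || !is.numeric(threshold) || length(threshold) != 1L ||
        threshold <= 0 || threshold >= 1)
      stop("an oet schedule requires a threshold strictly inside (0, 1)")
  } else if (!is.null(threshold)) {
    stop("threshold is only meaningful for kind = 'oet'")
  }
  s <- as.integer(nominal_spacing_trials)
  if (kind == "massed" && s != 0L)
    stop("massed means nominal_spacing_trials = 0")
  if (kind %in% c("uniform", "expanding", "contracting") && s == 0L)
    stop("spaced schedules need nominal_spacing_trials > 0")
  structure(list(kind = kind, nominal_spacing_trials = s,
                 reps_per_item = as.integer(reps_per_item),
                 jitter = isTRUE(jitter), threshold = threshold),
            class = "schedule_spec")
}

# Default gap profile for expanding/contracting schedules: an arithmetic
# progression over the repetitions that preserves the requested mean gap,
# running from mean/3 up to 5*mean/3 (reversed for contracting).
#' Gap profile of a fixed schedule
#'
#' Inter-repetition gap sequence (in schedule positions) used when laying
#' out fixed schedules: constant for uniform, an increasing arithmetic
#' progression from \code{mean_gap/3} to \code{5*mean_gap/3} for expanding
#' (mean preserved), and its reverse for contracting.
#'
#' @param kind \code{"uniform"}, \code{"expanding"} or \code{"contracting"}.
#' @param mean_gap target mean gap between repetitions.
#' @param n_gaps number of gaps (repetitions minus one).
#' @return Numeric vector of length \code{n_gaps} whose mean is
#'   \code{mean_gap}.
#' @export
#' @examples
#' spacing_profile("expanding", 15, 3)  # 5 15 25
spacing_profile <- function(kind = c("uniform", "expanding", "contracting"),
                            mean_gap, n_gaps) {
  kind <- match.arg(kind)
  if (n_gaps < 1L) return(numeric())
  if (kind == "uniform" || n_gaps == 1L) return(rep(mean_gap, n_gaps))
  g <- seq(mean_gap / 3, 5 * mean_gap / 3, length.out = n_gaps)
  if (kind == "contracting") g <- rev(g)
  g
}

# Stable linearization: order planned (possibly tied, possibly jittered)
# real-valued positions, breaking ties by original planning order.
linearize_plan <- function(item, pos) {
  item[order(pos, seq_along(pos))]
}

# Earliest-due-date layout: one slot per planned repetition; at each slot the
# item whose next planned position is earliest is placed, and its following
# repetition is re-anchored to the realized slot plus its planned gap.  This
# keeps every realized gap close to its per-item target even when the mix of
# gap profiles cannot tile the sequence exactly.
edf_sequence <- function(gap_list, starts, jitter = FALSE) {
  n_items <- length(gap_list)
  reps <- vapply(gap_list, length, 0L) + 1L
  total <- sum(reps)
  due <- starts
  gap_next <- vapply(gap_list, function(g)
    if (length(g) > 0L) g[1L] else Inf, 0)
  next_rep <- rep(1L, n_items)
  out <- integer(total)
  for (t in seq_len(total)) {
    avail <- which(next_rep <= reps)
    late <- due[avail] <= t
    pick <- if (any(late)) {
      # among due items, serve the one whose delay hurts most relative to
      # its target gap (narrow-spacing items are the most schedule-critical)
      cand <- avail[late]
      cand[which.max((t - due[cand]) / pmax(gap_next[cand], 1))]
    } else {
      avail[which.min(due[avail])]
    }
    out[t] <- pick
    k <- next_rep[pick]
    next_rep[pick] <- k + 1L
    if (k < reps[pick]) {
      g <- gap_list[[pick]][k]
      # a repetition served d slots late shortens the next target gap by d
      # (floored at 1), so each item's mean realized gap telescopes back to
      # its target despite queueing congestion
      d_late <- max(0, t - due[pick])
      due[pick] <- t + max(1, g - d_late +
                             if (jitter) sample(c(-1, 0, 1), 1L) else 0)
      gap_next[pick] <- g
    }
  }
  out
}

#' Build a conventional fixed practice schedule
#'
#' Lays out the full item sequence for a conventional schedule.  Massed
#' schedules place each item's repetitions consecutively.  Uniform schedules
#' cycle balanced cohorts of about \code{nominal_spacing_trials + 1} items,
#' giving approximately the nominal number of intervening trials.
#' Expanding/contracting schedules plan each item's repetitions at gaps
#' given by [spacing_profile()] (same mean gap as uniform) and linearize the
#' planned positions by stable ordering.  \code{"blocked_s15"} forms two
#' consecutive blocks of half the items each, maximally spaced within block.
#' With \code{jitter = TRUE} each planned repetition position is shifted by
#' -1/0/+1 uniformly before linearization.
#'
#' @param n_items number of distinct items (ids \code{1:n_items}).
#' @param spec a [schedule_spec()] of a conventional kind.
#' @param seed integer seed controlling item-order randomization and jitter.
#' @return Integer vector of item ids; every item appears exactly
#'   \code{reps_per_item} times.
#' @export
build_fixed_schedule <- function(n_items, spec, seed = 1L) {
  if (!spec$kind %in% c("massed", "uniform", "expanding", "contracting",
                        "blocked_s15"))
    stop("build_fixed_schedule handles conventional kinds only")
  reps <- spec$reps_per_item
  if (reps < 1L) stop("reps_per_item must be >= 1")
  n_items <- as.integer(n_items)
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old))
  set.seed(as.integer(seed))
  order_items <- sample.int(n_items)

  if (spec$kind == "massed") {
    plan_item <- rep(order_items, each = reps)
    plan_pos <- seq_along(plan_item)
  } else if (spec$kind %in% c("uniform", "blocked_s15")) {
    target <- if (spec$kind == "blocked_s15") {
      ceiling(n_items / 2)
    } else {
      spec$nominal_spacing_trials + 1L
    }
    n_cohorts <- max(1L, if (spec$kind == "blocked_s15") 2L else
      as.integer(round(n_items / target)))
    if (n_cohorts > n_items)
      stop("impossible spacing for the given number of items")
    cohort_of <- sort(rep_len(seq_len(n_cohorts), n_items))
    seqs <- lapply(seq_len(n_cohorts), function(b) {
      members <- order_items[cohort_of == b]
      rep(members, times = reps)      # cycle cohort: A B C A B C ...
    })
    plan_item <- unlist(seqs, use.names = FALSE)
    plan_pos <- seq_along(plan_item)
  } else {                             # expanding / contracting
    gaps <- spacing_profile(spec$kind, spec$nominal_spacing_trials + 1,
                            reps - 1L)
    total <- n_items * reps
    span <- sum(gaps)
    # stagger introductions over the room left by the common span; the
    # expanding profile congests the head of the sequence (its early gaps
    # are collectively infeasible), so its start range extends slightly
    # into the tail, where the squeeze on final gaps offsets the queueing
    # delay
    room <- if (spec$kind == "expanding") total - 0.8 * span else total - span
    starts <- seq(1, max(1, room), length.out = n_items)
    seq_idx <- edf_sequence(rep(list(gaps), n_items), starts,
                            jitter = spec$jitter)
    return(order_items[seq_idx])
  }
  if (spec$jitter)
    plan_pos <- plan_pos + sample(c(-1, 0, 1), length(plan_pos), replace = TRUE)
  linearize_plan(plan_item, plan_pos)
}

# Save/restore the global RNG state so seeded helpers do not disturb the
# caller's stream.
.Random.seed_save <- function() {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv()) else NULL
}
.Random.seed_restore <- function(old) {
  if (!is.null(old)) assign(".Random.seed", old, envir = globalenv())
}

#' Drop-1 heuristic state
#'
#' The Drop-1 heuristic cycles items round-robin in a fixed seeded order and
#' drops an item from the rotation once it is recalled successfully; when
#' every item has been dropped, all items are reinstated and the cycle
#' restarts.
#'
#' @param items vector of item ids.
#' @param seed integer seed fixing the presentation order.
#' @return An object of class \code{"drop1_state"}.
#' @seealso [next_item_drop1()]
#' @export
drop1_state <- function(items, seed = 1L) {
  old <- .Random.seed_save(); on.exit(.Random.seed_restore(old))
  set.seed(as.integer(seed))
  structure(list(order = sample(items), active = rep(TRUE, length(items)),
                 cursor = 0L, last = NA_integer_),
            class = "drop1_state")
}

#' Next item under the Drop-1 heuristic
#'
#' Applies the outcome of the previously selected item (a success drops it
#' from the rotation), reinstates all items if none remain active, then
#' advances round-robin to the next active item.
#'
#' @param state a [drop1_state()].
#' @param last_outcome outcome of the last selected item's trial:
#'   \code{"success"}, \code{"failure"} or \code{NULL}/\code{"none"} if
#'   there was none (first call, or a study trial).
#' @return A list with \code{item} (the selected id) and \code{state} (the
#'   updated state, to be passed to the next call).
#' @export
next_item_drop1 <- function(state, last_outcome = NULL) {
  if (!is.null(last_outcome) && identical(last_outcome, "success") &&
      !is.na(state$last)) {
    state$active[match(state$last, state$order)] <- FALSE
  }
  if (!any(state$active)) state$active[] <- TRUE   # restart
  n <- length(state$order)
  k <- state$cursor
  repeat {
    k <- k %% n + 1L
    if (state$active[k]) break
  }
  state$cursor <- k
  state$last <- state$order[k]
  list(item = state$order[k], state = state)
}

#' Next item under the optimal-efficiency-threshold policy
#'
#' Selects the item whose predicted recall probability is closest to, but
#' below, the threshold.  If every item is at or above the threshold, the
#' item closest to it (the minimum) is selected instead — which is also the
#' policy's natural mechanism for introducing new items, since unpracticed
#' items sit near their baseline probability.  Exact ties are broken
#' uniformly at random using the current RNG stream.
#'
#' @param predictions named (or plain) numeric vector of per-item predicted
#'   recall probabilities.
#' @param threshold recall-probability threshold, strictly inside (0, 1).
#' @return The index (or name, if \code{predictions} is named) of the
#'   selected item as an integer index into \code{predictions}.
#' @export
#' @examples
#' next_item_oet(c(A = 0.95, B = 0.80, C = 0.10), 0.94)  # selects B
next_item_oet <- function(predictions, threshold) {
  if (length(predictions) == 0L) stop("predictions must be non-empty")
  if (threshold <= 0 || threshold >= 1) stop("threshold must be in (0, 1)")
  below <- predictions < threshold
  cand <- if (any(below)) {
    which(below & predictions == max(predictions[below]))
  } else {
    which(predictions == min(predictions))
  }
  if (length(cand) > 1L) cand <- cand[sample.int(length(cand), 1L)]
  unname(cand)
}
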