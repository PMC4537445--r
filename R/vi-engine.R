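# Discrete-event simulator of the concurrent variable-interval schedule:
# each response side runs an independent VI reward schedule (intervals
# drawn uniformly from 0-40 s in 5-s steps, mean 20 s) and, in the
# punishment phase, an independent superimposed VI punishment schedule
# (20-60 s in 5-s steps, mean 40 s). The first response at or after an
# interval's elapse collects the armed outcome; the next interval starts
# only once that response has been made. If both schedules on a side have
# elapsed before the next response, that response takes the
# earlier-elapsed schedule's outcome and the following response takes the
# other; no single response carries two outcomes. Simultaneous elapses
# break in favour of the reward schedule.

#' Interval support of the two VI schedules
#'
#' @param kind `"reward"` (0-40 s in 5-s steps, mean 20 s) or
#'   `"punish"` (20-60 s in 5-s steps, mean 40 s).
#' @return Numeric vector of interval durations (seconds).
#' @export
vi_support <- function(kind = c("reward", "punish")) {
  kind <- match.arg(kind)
  if (kind == "reward") seq(0, 40, by = 5) else seq(20, 60, by = 5)
}

# run the coupled reward/punishment schedules over one side's response
# times; returns delivery times per outcome kind
run_side_schedules <- function(rt, duration, supports) {
  kinds <- names(supports)
  elapse <- vapply(supports, function(s)
    s[sample.int(length(s), 1L)], numeric(1))
  consumed <- logical(length(rt))
  out_time <- numeric(0); out_kind <- character(0)
  active <- rep(TRUE, length(kinds))
  while (any(active)) {
    # earliest-elapsed active schedule; ties favour the reward schedule,
    # which is listed first in `supports`
    k <- which(active)[which.min(elapse[active])]
    e <- elapse[k]
    if (e > duration) { active[k] <- FALSE; next }
    j <- findInterval(e, rt)
    if (j < 1L || rt[j] < e) j <- j + 1L
    while (j <= length(rt) && consumed[j]) j <- j + 1L
    if (j > length(rt) || rt[j] > duration) { active[k] <- FALSE; next }
    consumed[j] <- TRUE
    out_time <- c(out_time, rt[j]); out_kind <- c(out_kind, kinds[k])
    elapse[k] <- rt[j] + supports[[k]][sample.int(length(supports[[k]]), 1L)]
  }
  list(time = out_time, kind = out_kind)
}

#' Simulate one VI session
#'
#' @param responses list with strictly increasing response-time vectors
#'   `left` and `right` (seconds).
#' @param duration session duration in seconds.
#' @param phase `"reward_only"` or `"reward_punishment"` (punishment
#'   schedule superimposed).
#' @param reward_support,punish_support interval supports; defaults are
#'   the schedule's standard grids (see [vi_support()]).
#' @return Event log data frame `(time, side, kind)` sorted by time, with
#'   `kind` one of `response`, `reward`, `punish`; attributes `duration`
#'   and `phase`.
#' @export
simulate_vi_session <- function(responses, duration,
                                phase = c("reward_only",
                                          "reward_punishment"),
                                reward_support = vi_support("reward"),
                                punish_support = vi_support("punish")) {
  phase <- match.arg(phase)
  if (duration <= 0) stop("duration must be positive")
  if (!is.list(responses) ||
      !all(c("left", "right") %in% names(responses)))
    stop("responses must be a list with elements 'left' and 'right'")
  events <- list()
  for (side in c("left", "right")) {
    rt <- responses[[side]]
    if (length(rt) && any(diff(rt) <= 0))
      stop("response times must be strictly increasing per side")
    rt <- rt[rt <= duration]
    if (length(rt))
      events[[length(events) + 1L]] <- data.frame(
        time = rt, side = side, kind = "response",
        stringsAsFactors = FALSE)
    if (!length(rt)) next
    supports <- if (phase == "reward_only") {
      list(reward = reward_support)
    } else {
      list(reward = reward_support, punish = punish_support)
    }
    dl <- run_side_schedules(rt, duration, supports)
    if (length(dl$time))
      events[[length(events) + 1L]] <- data.frame(
        time = dl$time, side = side, kind = dl$kind,
        stringsAsFactors = FALSE)
  }
  log <- if (length(events)) do.call(rbind, events) else
    data.frame(time = numeric(0), side = character(0),
               kind = character(0), stringsAsFactors = FALSE)
  # stable order: time, then responses before the outcome they carry
  log <- log[order(log$time, log$side, log$kind != "response"), ]
  rownames(log) <- NULL
  structure(log, duration = duration, phase = phase)
}

#' Poisson (exponential inter-response) response times
#'
#' A convenience responder for simulations and tests.
#'
#' @param rate mean responses per second.
#' @param duration session duration (seconds).
#' @return Strictly increasing response times within `(0, duration]`.
#' @export
poisson_response_times <- function(rate, duration) {
  n <- max(10, ceiling(rate * duration * 1.5 + 10 * sqrt(rate * duration)))
  t <- cumsum(stats::rexp(n, rate))
  while (length(t) && t[length(t)] < duration)
    t <- c(t, t[length(t)] + cumsum(stats::rexp(n, rate)))
  t[t <= duration]
}

#' Response-suppression metrics across VI phases
#'
#' Per-session response counts per side, and the change in mean responding
#' from the reward-only phase to the punishment phase (negative =
#' suppression, positive = facilitation).
#'
#' @param logs list of event logs from [simulate_vi_session()], each
#'   carrying its `phase` attribute.
#' @return List: `sessions` (session, phase, left, right, total) and
#'   `change` (punishment-phase minus reward-only-phase mean counts, per
#'   side and total); `complete` is `FALSE` (with `NA` change and a
#'   warning) if a phase is missing.
#' @export
suppression_metrics <- function(logs) {
  if (!length(logs)) stop("need at least one session log")
  phases <- vapply(logs, function(l) attr(l, "phase"), character(1))
  counts <- lapply(logs, function(l) {
    r <- l[l$kind == "response", , drop = FALSE]
    c(left = sum(r$side == "left"), right = sum(r$side == "right"))
  })
  sessions <- data.frame(
    session = seq_along(logs), phase = phases,
    left = vapply(counts, `[[`, numeric(1), "left"),
    right = vapply(counts, `[[`, numeric(1), "right"))
  sessions$total <- sessions$left + sessions$right
  complete <- all(c("reward_only", "reward_punishment") %in% phases)
  if (!complete) {
    warning("missing a phase; change is NA")
    change <- c(left = NA_real_, right = NA_real_, total = NA_real_)
  } else {
    m <- function(col, ph) mean(sessions[[col]][sessions$phase == ph])
    change <- vapply(c("left", "right", "total"), function(col)
      m(col, "reward_punishment") - m(col, "reward_only"), numeric(1))
  }
  list(sessions = sessions, change = change, complete = complete)
}
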