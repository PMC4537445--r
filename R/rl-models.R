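# The eight-member softmax delta-rule model family.
#
# A model spec toggles three mechanisms: valence-split reinforcement rates
# (tau_r / tau_p instead of a single tau), stimulus stickiness (tau_c, d_c)
# and side stickiness (tau_l, d_l). Choice follows a softmax with inverse
# temperature fixed at 1 over x_i = v_i + c_i + l_side(i); mechanisms that
# are switched off contribute zero to x.

#' Define one member of the reinforcement-learning model family
#'
#' @param split_valence use separate reinforcement rates for reward
#'   (`tau_r`) and punishment (`tau_p`) rather than a single rate `tau`.
#' @param stim_stickiness include stimulus stickiness (`tau_c`, `d_c`), the
#'   outcome-independent tendency to repeat choices of recently chosen
#'   stimuli.
#' @param side_stickiness include side stickiness (`tau_l`, `d_l`), the
#'   same tendency attached to the left/right response side.
#'
#' @return An object of class `pvdrl_spec`.
#' @seealso [model_family()], [param_names()]
#' @export
model_spec <- function(split_valence = FALSE, stim_stickiness = FALSE,
                       side_stickiness = FALSE) {
  stopifnot(is.logical(split_valence), is.logical(stim_stickiness),
            is.logical(side_stickiness))
  structure(
    list(split_valence = isTRUE(split_valence),
         stim_stickiness = isTRUE(stim_stickiness),
         side_stickiness = isTRUE(side_stickiness)),
    class = "pvdrl_spec")
}

#' @export
print.pvdrl_spec <- function(x, ...) {
  cat("RL model spec:", spec_label(x), "(", n_params(x), "parameters/subject )\n")
  invisible(x)
}

#' Enumerate the full model family
#'
#' All 2 x 2 x 2 combinations of valence splitting, stimulus stickiness and
#' side stickiness, in a stable order (single-rate, no-stickiness model
#' first).
#'
#' @return A named list of 8 `pvdrl_spec` objects.
#' @export
model_family <- function() {
  grid <- expand.grid(side = c(FALSE, TRUE), stim = c(FALSE, TRUE),
                      split = c(FALSE, TRUE))
  specs <- lapply(seq_len(nrow(grid)), function(i)
    model_spec(grid$split[i], grid$stim[i], grid$side[i]))
  names(specs) <- vapply(specs, spec_label, character(1))
  specs
}

#' Short label for a model spec
#'
#' @param spec a `pvdrl_spec`.
#' @return A character scalar such as `"tau+stim+side"`.
#' @export
spec_label <- function(spec) {
  paste0(if (spec$split_valence) "tau_rp" else "tau",
         if (spec$stim_stickiness) "+stim" else "",
         if (spec$side_stickiness) "+side" else "")
}

#' Names of the free parameters of a model spec
#'
#' @param spec a `pvdrl_spec`.
#' @return Character vector: a subset of `tau`, `tau_r`, `tau_p`, `tau_c`,
#'   `d_c`, `tau_l`, `d_l`, in canonical order.
#' @export
param_names <- function(spec) {
  stopifnot(inherits(spec, "pvdrl_spec"))
  c(if (spec$split_valence) c("tau_r", "tau_p") else "tau",
    if (spec$stim_stickiness) c("tau_c", "d_c"),
    if (spec$side_stickiness) c("tau_l", "d_l"))
}

#' Number of free parameters per subject
#'
#' @param spec a `pvdrl_spec`.
#' @return Integer between 1 and 6.
#' @export
n_params <- function(spec) length(param_names(spec))

#' Construct and validate a parameter set
#'
#' Rates (every parameter named `tau*`) must lie in `[0, 1]`; stickiness
#' maxima (`d_c`, `d_l`) must be nonnegative. The softmax inverse
#' temperature is fixed at 1 and is not a free parameter.
#'
#' @param ... named parameter values, or a single named numeric vector.
#' @param spec a `pvdrl_spec` the values must match exactly.
#' @return Named numeric vector in canonical order.
#' @export
param_set <- function(..., spec) {
  dots <- list(...)
  x <- if (length(dots) == 1L && is.null(names(dots)) &&
           is.numeric(dots[[1]]) && !is.null(names(dots[[1]]))) {
    dots[[1]]
  } else {
    unlist(dots)
  }
  wanted <- param_names(spec)
  missing <- setdiff(wanted, names(x))
  extra <- setdiff(names(x), wanted)
  if (length(missing))
    stop("missing parameters for spec '", spec_label(spec), "': ",
         paste(missing, collapse = ", "))
  if (length(extra))
    stop("parameters not in spec '", spec_label(spec), "': ",
         paste(extra, collapse = ", "))
  x <- x[wanted]
  rates <- startsWith(wanted, "tau")
  if (any(x[rates] < 0 | x[rates] > 1))
    stop("rate parameters must lie in [0, 1]")
  if (any(x[!rates] < 0))
    stop("stickiness maxima must be nonnegative")
  x
}

# is each parameter a rate (vs a stickiness maximum)?
param_is_rate <- function(nm) startsWith(nm, "tau")

# slot codes used by the C++ core; see rl_core.cpp
param_slots <- function(spec) {
  codes <- c(tau = 0L, tau_r = 1L, tau_p = 2L, tau_c = 3L, d_c = 4L,
             tau_l = 5L, d_l = 6L)
  unname(codes[param_names(spec)])
}

# expand a named parameter set to the fixed 6-vector the C++ core takes:
# (tau_r, tau_p, tau_c, d_c, tau_l, d_l); absent mechanisms stay 0
par6 <- function(params, spec) {
  p <- c(tau_r = 0, tau_p = 0, tau_c = 0, d_c = 0, tau_l = 0, d_l = 0)
  if (spec$split_valence) {
    p["tau_r"] <- params[["tau_r"]]; p["tau_p"] <- params[["tau_p"]]
  } else {
    p["tau_r"] <- p["tau_p"] <- params[["tau"]]
  }
  if (spec$stim_stickiness) {
    p["tau_c"] <- params[["tau_c"]]; p["d_c"] <- params[["d_c"]]
  }
  if (spec$side_stickiness) {
    p["tau_l"] <- params[["tau_l"]]; p["d_l"] <- params[["d_l"]]
  }
  unname(p)
}

#' Initialise an agent state for a stimulus pair
#'
#' @param stimuli character vector of two stimulus ids.
#' @return A list with reinforcement values `v` (per stimulus), stimulus
#'   stickiness `c` (per stimulus), and side stickiness `l`
#'   (`left`/`right`), all starting at zero.
#' @export
agent_state <- function(stimuli) {
  stopifnot(length(stimuli) == 2L, !anyDuplicated(stimuli))
  stimuli <- as.character(stimuli)
  list(v = setNames(c(0, 0), stimuli),
       c = setNames(c(0, 0), stimuli),
       l = c(left = 0, right = 0))
}

#' Softmax choice probabilities for the offered pair
#'
#' Each stimulus is valued as `x = v + c + l[side]` and choice follows a
#' softmax with inverse temperature 1, so
#' `P(i) = exp(x_i) / (exp(x_1) + exp(x_2))`.
#'
#' @param state an [agent_state()].
#' @param stim_pair character vector of the two offered stimulus ids.
#' @param side_assignment named character vector `c(left = ..., right = ...)`
#'   stating which stimulus is on which side.
#' @return Named probability vector over `stim_pair`; sums to 1.
#' @export
choice_probabilities <- function(state, stim_pair,
                                 side_assignment = c(left = stim_pair[1],
                                                     right = stim_pair[2])) {
  stim_pair <- as.character(stim_pair)
  if (!all(stim_pair %in% names(state$v)))
    stop("unknown stimulus id: ",
         paste(setdiff(stim_pair, names(state$v)), collapse = ", "))
  if (!setequal(names(side_assignment), c("left", "right")) ||
      !setequal(side_assignment, stim_pair))
    stop("side_assignment must place exactly the offered pair on left/right")
  side_of <- setNames(names(side_assignment), side_assignment)
  x <- vapply(stim_pair, function(s)
    state$v[[s]] + state$c[[s]] + state$l[[side_of[[s]]]], numeric(1))
  e <- exp(x - max(x))
  e / sum(e)
}

#' Apply one trial's learning update to an agent state
#'
#' The chosen stimulus's value follows a delta rule,
#' `v <- v + tau * (r - v)` with reinforcement `r = +1` for reward and
#' `-1` for punishment (rate `tau_r`/`tau_p` when valences are split);
#' the unchosen value is untouched. Stickiness traces track a choice
#' indicator scaled to their maximum:
#' `c_chosen <- c_chosen + tau_c * (d_c - c_chosen)` and
#' `c_unchosen <- (1 - tau_c) * c_unchosen`, and identically for side
#' stickiness `l` over `left`/`right`. Mechanisms absent from `spec` leave
#' their traces at zero.
#'
#' @param state an [agent_state()].
#' @param choice_stim id of the chosen stimulus.
#' @param choice_side `"left"` or `"right"`.
#' @param outcome `"reward"` or `"punish"`.
#' @param params parameter set matching `spec`.
#' @param spec a `pvdrl_spec`.
#' @return The updated state.
#' @export
update_state <- function(state, choice_stim, choice_side, outcome, params,
                         spec) {
  stopifnot(choice_stim %in% names(state$v),
            choice_side %in% c("left", "right"),
            outcome %in% c("reward", "punish"))
  r <- if (outcome == "reward") 1 else -1
  tau <- if (spec$split_valence) {
    if (r > 0) params[["tau_r"]] else params[["tau_p"]]
  } else params[["tau"]]
  state$v[[choice_stim]] <- state$v[[choice_stim]] +
    tau * (r - state$v[[choice_stim]])
  if (spec$stim_stickiness) {
    ind <- as.numeric(names(state$c) == choice_stim)
    state$c <- state$c + params[["tau_c"]] * (params[["d_c"]] * ind - state$c)
  }
  if (spec$side_stickiness) {
    ind <- as.numeric(names(state$l) == choice_side)
    state$l <- state$l + params[["tau_l"]] * (params[["d_l"]] * ind - state$l)
  }
  state
}

#' Log-likelihood of a recorded trial sequence
#'
#' Sums, over trials, the log softmax probability of the recorded choice
#' evaluated at the state *before* that trial's update; the update is then
#' applied. State starts at zero and follows the stage-reset policy:
#' reinforcement values `v` and stimulus stickiness `c` are zeroed at the
#' start of any stage introducing a new stimulus pair (reversals keep the
#' pair, so keep the state); side stickiness `l` persists throughout.
#'
#' This is the plain-R reference implementation; fitting routines use a
#' compiled equivalent that is tested against it.
#'
#' @param trials a trial-log data frame for a single subject (see
#'   [simulate_cohort()] for the column contract).
#' @param params parameter set matching `spec`.
#' @param spec a `pvdrl_spec`.
#' @return Log-likelihood (scalar).
#' @export
session_loglik <- function(trials, params, spec) {
  trials <- validate_trials(trials, single_subject = TRUE)
  params <- param_set(params, spec = spec)
  ll <- 0
  state <- NULL
  prev_pair <- NULL
  for (stage in unique(trials$stage)) {
    st <- trials[trials$stage == stage, , drop = FALSE]
    pair <- sort(unique(c(st$stim_left, st$stim_right)))
    if (is.null(state)) {
      state <- agent_state(pair)
    } else if (!identical(pair, prev_pair)) {
      l_keep <- state$l
      state <- agent_state(pair)
      state$l <- l_keep
    }
    prev_pair <- pair
    for (i in seq_len(nrow(st))) {
      pr <- choice_probabilities(
        state, pair,
        side_assignment = c(left = st$stim_left[i], right = st$stim_right[i]))
      ll <- ll + log(pr[[st$choice_stim[i]]])
      state <- update_state(state, st$choice_stim[i], st$choice_side[i],
                            st$outcome[i], params, spec)
    }
  }
  ll
}

# ---- trial-log plumbing shared across modules ----

trial_columns <- c("subject", "group", "stage", "session", "trial",
                   "stim_left", "stim_right", "correct_stim", "choice_stim",
                   "choice_side", "outcome", "veracity")

validate_trials <- function(trials, single_subject = FALSE) {
  if (!is.data.frame(trials) || nrow(trials) == 0L)
    stop("trials must be a non-empty data frame")
  missing <- setdiff(trial_columns, names(trials))
  if (length(missing))
    stop("trial log lacks columns: ", paste(missing, collapse = ", "))
  if (single_subject && length(unique(trials$subject)) != 1L)
    stop("expected trials from a single subject")
  bad <- trials$choice_stim != trials$stim_left &
    trials$choice_stim != trials$stim_right
  if (any(bad))
    stop("choice_stim must be one of the offered pair")
  # within each subject x stage x session, trial indices must increase
  key <- interaction(trials$subject, trials$stage, trials$session,
                     drop = TRUE)
  mono <- tapply(trials$trial, key, function(x) all(diff(x) > 0))
  if (!all(unlist(mono)))
    stop("non-monotone trial indices within a session")
  trials
}

# Encode one subject's ordered trials for the C++ core. Stimulus index 1 is
# the alphabetically first member of each stage's pair; reset marks stage
# starts whose pair differs from the preceding stage's pair.
encode_subject <- function(trials) {
  n <- nrow(trials)
  chosen <- integer(n); side1 <- integer(n); reset <- integer(n)
  reinf <- ifelse(trials$outcome == "reward", 1, -1)
  prev_pair <- NULL
  row <- 1L
  for (stage in unique(trials$stage)) {
    idx <- which(trials$stage == stage)
    st <- trials[idx, , drop = FALSE]
    pair <- sort(unique(c(st$stim_left, st$stim_right)))
    if (length(pair) != 2L)
      stop("each stage must present exactly one stimulus pair")
    reset[idx[1]] <- as.integer(!identical(pair, prev_pair))
    prev_pair <- pair
    chosen[idx] <- ifelse(st$choice_stim == pair[1], 1L, 2L)
    side1[idx] <- ifelse(st$stim_left == pair[1], 1L, 2L)
  }
  list(chosen = chosen, side1 = side1, reinf = reinf, reset = reset)
}

# fast compiled log-likelihood on an encoded subject
loglik_encoded <- function(enc, params, spec) {
  rl_loglik_cpp(enc$chosen, enc$side1, enc$reinf, enc$reset,
                par6(params, spec), spec$stim_stickiness,
                spec$side_stickiness)
}

# split a cohort trial log into per-subject encodings (ordered as given)
encode_trials <- function(trials) {
  trials <- validate_trials(trials)
  subjects <- unique(trials$subject)
  enc <- lapply(subjects, function(s)
    encode_subject(trials[trials$subject == s, , drop = FALSE]))
  names(enc) <- subjects
  groups <- vapply(subjects, function(s)
    as.character(trials$group[trials$subject == s][1]), character(1))
  list(enc = enc, subjects = as.character(subjects), groups = groups)
}
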