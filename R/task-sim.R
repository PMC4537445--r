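# Simulation of the probabilistic visual discrimination / reversal task.
#
# A stage presents one pair of stimuli; within a session each stimulus
# appears equally often on the left and right. A choice of the currently
# correct stimulus is rewarded with probability p_valid and punished
# otherwise (the inverse for the incorrect stimulus). Sessions repeat until
# one reaches the correct-fraction criterion (or max_sessions). Reversal
# stages keep the parent stage's stimuli with the contingency flipped.

#' Configuration for one discrimination stage
#'
#' @param stage_id label, e.g. `"D5"`.
#' @param p_valid valid-reinforcement probability in `[0.5, 1]`: the chance
#'   that feedback is congruent with the current contingency (0.8 in most
#'   stages, 0.7 in one).
#' @param trials_per_session trials per session (even, so sides balance);
#'   40 emulates the animal protocol, 30 the virtual-subject protocol.
#' @param criterion session-level correct fraction at which the stage ends
#'   (the comparison is `>=`).
#' @param max_sessions hard cap guaranteeing termination.
#' @param punishment_present whether the aversive outcome is delivered
#'   (bookkeeping only; the model codes both outcomes identically).
#' @param reversal_of optional `stage_id` of the parent stage whose
#'   contingency this stage reverses.
#' @return A `pvdrl_stage` list.
#' @export
stage_config <- function(stage_id, p_valid = 0.8, trials_per_session = 40L,
                         criterion = 0.9, max_sessions = 100L,
                         punishment_present = TRUE, reversal_of = NULL) {
  if (p_valid < 0.5 || p_valid > 1)
    stop("p_valid must lie in [0.5, 1]")
  trials_per_session <- as.integer(trials_per_session)
  if (trials_per_session <= 0L || trials_per_session %% 2L != 0L)
    stop("trials_per_session must be a positive even integer")
  if (criterion <= 0 || criterion > 1)
    stop("criterion must lie in (0, 1]")
  max_sessions <- as.integer(max_sessions)
  if (max_sessions < 1L) stop("max_sessions must be >= 1")
  structure(list(stage_id = as.character(stage_id), p_valid = p_valid,
                 trials_per_session = trials_per_session,
                 criterion = criterion, max_sessions = max_sessions,
                 punishment_present = isTRUE(punishment_present),
                 reversal_of = reversal_of),
            class = "pvdrl_stage")
}

#' Draw the probabilistic outcome of one or more choices
#'
#' A correct choice is rewarded with probability `p_valid` and punished
#' otherwise; an incorrect choice is rewarded with probability
#' `1 - p_valid`. Feedback is "true" (veracious) when it is congruent with
#' the contingency: reward for a correct choice or punishment for an
#' incorrect one.
#'
#' @param is_correct logical vector.
#' @param p_valid valid-reinforcement probability in `[0.5, 1]`.
#' @return Data frame with columns `outcome` (`"reward"`/`"punish"`) and
#'   `veracity` (logical).
#' @export
assign_outcome <- function(is_correct, p_valid) {
  if (!is.numeric(p_valid) || length(p_valid) != 1 ||
      p_valid < 0.5 || p_valid > 1)
    stop("p_valid must be a single probability in [0.5, 1]")
  stopifnot(is.logical(is_correct))
  p_reward <- ifelse(is_correct, p_valid, 1 - p_valid)
  reward <- runif(length(is_correct)) < p_reward
  data.frame(outcome = ifelse(reward, "reward", "punish"),
             veracity = reward == is_correct,
             stringsAsFactors = FALSE)
}

# assemble TrialRecord rows from the C++ simulator's output
build_trial_records <- function(sim, pair, correct_stim, subject, group,
                                stage_id) {
  stim1 <- pair[1]; stim2 <- pair[2]
  stim_left <- ifelse(sim$side1 == 1L, stim1, stim2)
  stim_right <- ifelse(sim$side1 == 1L, stim2, stim1)
  choice_stim <- ifelse(sim$chosen == 1L, stim1, stim2)
  choice_side <- ifelse(choice_stim == stim_left, "left", "right")
  outcome <- ifelse(sim$reinf > 0, "reward", "punish")
  veracity <- (outcome == "reward") == (choice_stim == correct_stim)
  data.frame(subject = subject, group = group, stage = stage_id,
             session = sim$session, trial = sim$trial,
             stim_left = stim_left, stim_right = stim_right,
             correct_stim = correct_stim, choice_stim = choice_stim,
             choice_side = choice_side, outcome = outcome,
             veracity = veracity, stringsAsFactors = FALSE)
}

stage_stimuli <- function(cfg) paste0(cfg$stage_id, c("_A", "_B"))

#' Simulate a single session
#'
#' Runs exactly one session of `cfg$trials_per_session` trials with a
#' model-driven agent, drawing each choice from the softmax probabilities
#' and updating the agent after every trial.
#'
#' @param state an [agent_state()] dimensioned for the stage's pair.
#' @param params,spec the generating model.
#' @param cfg a [stage_config()].
#' @param stimuli the stimulus pair (defaults to ids derived from
#'   `cfg$stage_id`).
#' @param correct_stim the currently correct stimulus (defaults to the
#'   first of `stimuli`).
#' @param subject,group,session labels recorded in the output.
#' @return List with `trials` (the TrialRecord data frame) and `state`
#'   (the updated agent).
#' @export
simulate_session <- function(state, params, spec, cfg,
                             stimuli = stage_stimuli(cfg),
                             correct_stim = stimuli[1], subject = "s1",
                             group = "g1", session = 1L) {
  params <- param_set(params, spec = spec)
  pair <- sort(as.character(stimuli))
  if (!setequal(names(state$v), pair))
    stop("agent state is dimensioned for a different stimulus pair")
  if (!correct_stim %in% pair) stop("correct_stim must be one of the pair")
  sim <- rl_simulate_stage_cpp(par6(params, spec), spec$stim_stickiness,
                               spec$side_stickiness,
                               match(correct_stim, pair), cfg$p_valid,
                               cfg$trials_per_session, 1.0, 1L,
                               state$v[pair], state$c[pair],
                               state$l[c("left", "right")])
  trials <- build_trial_records(sim, pair, correct_stim, subject, group,
                                cfg$stage_id)
  trials$session <- session
  state$v[pair] <- sim$v; state$c[pair] <- sim$c
  state$l[c("left", "right")] <- sim$l
  list(trials = trials, state = state)
}

#' Simulate a whole stage (sessions until criterion)
#'
#' Sessions run until one attains a correct fraction `>= cfg$criterion` or
#' `cfg$max_sessions` is reached; agent state persists across sessions.
#' Besides the model-driven agent, scripted policies are available for
#' testing: `"always_correct"`, `"always_incorrect"`, and `"random"`
#' (indifferent).
#'
#' @inheritParams simulate_session
#' @param state optional starting [agent_state()]; a zeroed state for the
#'   pair is created if omitted.
#' @param policy `"model"` or one of the scripted policies above.
#' @return TrialRecord data frame with attributes `state` (final agent
#'   state), `n_sessions` and `attained`.
#' @export
simulate_stage <- function(params = NULL, spec = NULL, cfg,
                           stimuli = stage_stimuli(cfg),
                           correct_stim = stimuli[1], state = NULL,
                           subject = "s1", group = "g1",
                           policy = c("model", "always_correct",
                                      "always_incorrect", "random")) {
  policy <- match.arg(policy)
  pair <- sort(as.character(stimuli))
  if (!correct_stim %in% pair) stop("correct_stim must be one of the pair")
  if (policy != "model")
    return(simulate_stage_scripted(policy, cfg, pair, correct_stim, subject,
                                   group))
  params <- param_set(params, spec = spec)
  if (is.null(state)) state <- agent_state(pair)
  if (!setequal(names(state$v), pair))
    stop("agent state is dimensioned for a different stimulus pair")
  sim <- rl_simulate_stage_cpp(par6(params, spec), spec$stim_stickiness,
                               spec$side_stickiness,
                               match(correct_stim, pair), cfg$p_valid,
                               cfg$trials_per_session, cfg$criterion,
                               cfg$max_sessions, state$v[pair],
                               state$c[pair], state$l[c("left", "right")])
  trials <- build_trial_records(sim, pair, correct_stim, subject, group,
                                cfg$stage_id)
  state$v[pair] <- sim$v; state$c[pair] <- sim$c
  state$l[c("left", "right")] <- sim$l
  structure(trials, state = state, n_sessions = sim$n_sessions,
            attained = sim$attained)
}

# deterministic / indifferent policies used in tests and as degenerate
# baselines; outcomes still follow assign_outcome()
simulate_stage_scripted <- function(policy, cfg, pair, correct_stim,
                                    subject, group) {
  T <- cfg$trials_per_session; half <- T %/% 2L
  out <- vector("list", cfg$max_sessions)
  attained <- FALSE; ses <- 0L
  for (s in seq_len(cfg$max_sessions)) {
    ses <- s
    side1 <- sample(rep(1:2, each = half))
    choice_stim <- switch(policy,
      always_correct = rep(correct_stim, T),
      always_incorrect = rep(setdiff(pair, correct_stim), T),
      random = pair[sample(1:2, T, replace = TRUE)])
    is_correct <- choice_stim == correct_stim
    oc <- assign_outcome(is_correct, cfg$p_valid)
    sim <- list(session = rep(s, T), trial = seq_len(T), side1 = side1,
                chosen = match(choice_stim, pair),
                reinf = ifelse(oc$outcome == "reward", 1, -1))
    out[[s]] <- build_trial_records(sim, pair, correct_stim, subject, group,
                                    cfg$stage_id)
    if (mean(is_correct) >= cfg$criterion) { attained <- TRUE; break }
  }
  structure(do.call(rbind, out[seq_len(ses)]), state = NULL,
            n_sessions = ses, attained = attained)
}

#' Define a cohort simulation plan
#'
#' @param groups named list, one entry per group: either a named parameter
#'   vector shared by all of the group's subjects, or a list with elements
#'   `mean` and `sd` (named vectors) from which each subject's parameters
#'   are drawn as truncated normals (rates to `[0, 1]`, maxima to
#'   `[0, Inf)`).
#' @param subjects_per_group number of subjects per group.
#' @param stages ordered list of [stage_config()]s.
#' @param spec the generating `pvdrl_spec`.
#' @param seed integer seed recorded in the output.
#' @return A `pvdrl_plan` list.
#' @export
simulation_plan <- function(groups, subjects_per_group, stages, spec, seed) {
  if (is.null(names(groups)) || anyDuplicated(names(groups)))
    stop("groups must be uniquely named")
  if (!length(stages)) stop("stages must be non-empty")
  stopifnot(all(vapply(stages, inherits, logical(1), "pvdrl_stage")))
  structure(list(groups = groups,
                 subjects_per_group = as.integer(subjects_per_group),
                 stages = stages, spec = spec, seed = as.integer(seed)),
            class = "pvdrl_plan")
}

# truncated-normal subject draws for group-level parameter distributions
rtnorm <- function(n, mean, sd, lower, upper) {
  plo <- pnorm(lower, mean, sd); phi <- pnorm(upper, mean, sd)
  qnorm(runif(n, plo, phi), mean, sd)
}

draw_subject_params <- function(group_def, spec) {
  if (is.numeric(group_def)) return(param_set(group_def, spec = spec))
  nm <- param_names(spec)
  rate <- param_is_rate(nm)
  m <- group_def$mean[nm]; s <- group_def$sd[nm]
  if (anyNA(m) || anyNA(s))
    stop("group distribution must name every spec parameter in mean and sd")
  val <- vapply(seq_along(nm), function(j)
    rtnorm(1, m[j], s[j], 0, if (rate[j]) 1 else Inf), numeric(1))
  param_set(setNames(val, nm), spec = spec)
}

#' Simulate a full cohort from a plan
#'
#' One trial log per subject x stage, concatenated. Each subject gets a
#' private random stream derived from the plan seed, so the cohort is
#' reproducible and insensitive to subject ordering. State carries over
#' stages per the reset policy: `v` and `c` are zeroed when a stage brings
#' a new stimulus pair, reversal stages keep the parent pair and state with
#' the contingency flipped, and side stickiness `l` persists throughout.
#'
#' @param plan a [simulation_plan()].
#' @return TrialRecord data frame with attributes `seed`, `params`
#'   (per-subject generating values) and `plan_hash`.
#' @export
simulate_cohort <- function(plan) {
  stopifnot(inherits(plan, "pvdrl_plan"))
  spec <- plan$spec
  stage_ids <- vapply(plan$stages, `[[`, character(1), "stage_id")
  if (anyDuplicated(stage_ids)) stop("duplicate stage ids in plan")
  subj_idx <- 0L
  logs <- list(); gen_params <- list()
  for (g in names(plan$groups)) {
    for (i in seq_len(plan$subjects_per_group)) {
      subj_idx <- subj_idx + 1L
      subject <- sprintf("%s_s%02d", g, i)
      set.seed(as.integer((plan$seed + 48271 * subj_idx) %% 2147483647))
      params <- draw_subject_params(plan$groups[[g]], spec)
      gen_params[[subject]] <- params
      state <- NULL
      stage_pair <- list(); stage_correct <- list()
      prev_pair <- NULL
      for (cfg in plan$stages) {
        if (is.null(cfg$reversal_of)) {
          pair <- sort(stage_stimuli(cfg))
          correct <- pair[1]
        } else {
          parent <- as.character(cfg$reversal_of)
          if (is.null(stage_pair[[parent]]))
            stop("reversal_of refers to unknown stage: ", parent)
          pair <- stage_pair[[parent]]
          correct <- setdiff(pair, stage_correct[[parent]])
        }
        stage_pair[[cfg$stage_id]] <- pair
        stage_correct[[cfg$stage_id]] <- correct
        if (is.null(state) || !identical(pair, prev_pair)) {
          l_keep <- if (is.null(state)) c(left = 0, right = 0) else state$l
          state <- agent_state(pair)
          state$l <- l_keep
        }
        prev_pair <- pair
        st <- simulate_stage(params, spec, cfg, stimuli = pair,
                             correct_stim = correct, state = state,
                             subject = subject, group = g)
        state <- attr(st, "state")
        logs[[length(logs) + 1L]] <- as.data.frame(st)
      }
    }
  }
  out <- do.call(rbind, logs)
  rownames(out) <- NULL
  structure(out, seed = plan$seed, params = gen_params,
            plan_hash = plan_hash(plan))
}

# a cheap content hash for provenance records (no external digest dep)
plan_hash <- function(plan) {
  txt <- paste(deparse(plan), collapse = "")
  sprintf("%08x", sum(utf8ToInt(txt) * (seq_along(utf8ToInt(txt)) %% 251)) %%
            .Machine$integer.max)
}

#' Write / read a trial log as tab-separated text
#'
#' The header is exactly the TrialRecord field names in documented order;
#' logicals are written as `true`/`false`. `write_trial_log()` can append a
#' provenance line (seed, plan hash, package version) to a run-log file.
#'
#' @param trials TrialRecord data frame.
#' @param path output file.
#' @param run_log optional path of a provenance log to append to.
#' @return `path`, invisibly.
#' @export
write_trial_log <- function(trials, path, run_log = NULL) {
  trials <- validate_trials(trials)
  out <- trials[, trial_columns]
  out$veracity <- ifelse(out$veracity, "true", "false")
  utils::write.table(out, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  if (!is.null(run_log)) {
    line <- sprintf("%s\tseed=%s\tplan_hash=%s\tpvdrl=%s\t%s",
                    format(Sys.time(), "%Y-%m-%dT%H:%M:%S"),
                    attr(trials, "seed") %||% "NA",
                    attr(trials, "plan_hash") %||% "NA",
                    as.character(utils::packageVersion("pvdrl")), path)
    cat(line, "\n", file = run_log, append = TRUE, sep = "")
  }
  invisible(path)
}

#' @rdname write_trial_log
#' @export
read_trial_log <- function(path) {
  x <- utils::read.table(path, header = TRUE, sep = "\t",
                         stringsAsFactors = FALSE)
  x$veracity <- x$veracity == "true"
  validate_trials(x)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
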