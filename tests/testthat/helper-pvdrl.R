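# Shared fixtures and independent oracles for the test suite.

# Build a single-subject, single-stage trial log by hand. Stimuli are "A"
# and "B"; A is correct unless stated otherwise. `sides` gives the side of
# the chosen stimulus; stimulus placement is derived from it.
hand_trials <- function(choices, outcomes,
                        sides = rep("left", length(choices)),
                        correct = "A", stage = "D5", session = 1L,
                        subject = "s1", group = "g1") {
  stopifnot(length(choices) == length(outcomes))
  stim_left <- ifelse(sides == "left", choices,
                      ifelse(choices == "A", "B", "A"))
  stim_right <- ifelse(stim_left == "A", "B", "A")
  data.frame(
    subject = subject, group = group, stage = stage, session = session,
    trial = seq_along(choices), stim_left = stim_left,
    stim_right = stim_right, correct_stim = correct,
    choice_stim = choices, choice_side = sides,
    outcome = outcomes,
    veracity = (outcomes == "reward") == (choices == correct),
    stringsAsFactors = FALSE)
}

# Independent trial-by-trial log-likelihood oracle, written directly from
# the model definition (softmax over x = v + c + l with beta = 1; delta
# rule on the chosen value; exponential stickiness tracking). Deliberately
# free-standing: it shares no code with the package internals.
oracle_loglik <- function(trials, pars, split_valence, stim_stick,
                          side_stick) {
  v <- c(A = 0, B = 0); cs <- c(A = 0, B = 0); l <- c(left = 0, right = 0)
  ll <- 0
  for (i in seq_len(nrow(trials))) {
    side_of <- c(A = "", B = "")
    side_of[trials$stim_left[i]] <- "left"
    side_of[trials$stim_right[i]] <- "right"
    x <- c(A = v[["A"]] + cs[["A"]] + l[[side_of[["A"]]]],
           B = v[["B"]] + cs[["B"]] + l[[side_of[["B"]]]])
    p_choice <- exp(x[[trials$choice_stim[i]]]) / sum(exp(x))
    ll <- ll + log(p_choice)
    r <- if (trials$outcome[i] == "reward") 1 else -1
    rate <- if (split_valence) {
      if (r > 0) pars[["tau_r"]] else pars[["tau_p"]]
    } else pars[["tau"]]
    ch <- trials$choice_stim[i]
    v[[ch]] <- v[[ch]] + rate * (r - v[[ch]])
    if (stim_stick) {
      for (s in c("A", "B")) {
        tgt <- if (s == ch) pars[["d_c"]] else 0
        cs[[s]] <- cs[[s]] + pars[["tau_c"]] * (tgt - cs[[s]])
      }
    }
    if (side_stick) {
      for (s in c("left", "right")) {
        tgt <- if (s == trials$choice_side[i]) pars[["d_l"]] else 0
        l[[s]] <- l[[s]] + pars[["tau_l"]] * (tgt - l[[s]])
      }
    }
  }
  ll
}

# a full parameter vector usable with any spec (subsetting happens in
# param_set)
full_pars <- c(tau = 0.4, tau_r = 0.5, tau_p = 0.3, tau_c = 0.35,
               d_c = 0.8, tau_l = 0.25, d_l = 0.6)

pars_for <- function(spec) param_set(full_pars[param_names(spec)],
                                     spec = spec)

# a fixed 10-trial hand log exercising both sides, both outcomes and both
# stimuli
ten_trial_log <- function() {
  hand_trials(
    choices = c("A", "A", "B", "A", "B", "B", "A", "A", "B", "A"),
    outcomes = c("reward", "punish", "reward", "reward", "punish",
                 "reward", "punish", "reward", "reward", "punish"),
    sides = c("left", "right", "right", "left", "left", "right", "left",
              "right", "left", "right"))
}
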