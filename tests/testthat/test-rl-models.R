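test_that("the model family enumerates all eight mechanism combinations", {
  fam <- model_family()
  expect_length(fam, 8L)
  expect_false(anyDuplicated(names(fam)) > 0)
  zs <- unname(sort(vapply(fam, n_params, integer(1))))
  expect_equal(zs, c(1L, 2L, 3L, 3L, 4L, 4L, 5L, 6L))
  expect_equal(n_params(model_spec(TRUE, TRUE, TRUE)), 6L)
  expect_equal(n_params(model_spec()), 1L)
  expect_equal(param_names(model_spec(split_valence = TRUE)),
               c("tau_r", "tau_p"))
})

test_that("parameter sets are validated against their spec", {
  spec <- model_spec(stim_stickiness = TRUE)
  expect_error(param_set(tau = 0.5, spec = spec), "missing")
  expect_error(param_set(tau = 0.5, tau_c = 0.2, d_c = 1, d_l = 1,
                         spec = spec), "not in spec")
  expect_error(param_set(tau = 1.2, tau_c = 0.2, d_c = 1, spec = spec),
               "rate")
  expect_error(param_set(tau = 0.5, tau_c = 0.2, d_c = -1, spec = spec),
               "nonnegative")
})

test_that("softmax choice probabilities match closed forms", {
  st <- agent_state(c("A", "B"))
  expect_equal(choice_probabilities(st, c("A", "B")),
               c(A = 0.5, B = 0.5))
  st$v["A"] <- 1
  p <- choice_probabilities(st, c("A", "B"))
  expect_equal(unname(p["A"]), exp(1) / (1 + exp(1)), tolerance = 1e-12)
  # shift invariance: x = (0.5, -0.5) gives the same probabilities
  st2 <- agent_state(c("A", "B"))
  st2$v <- c(A = 0.5, B = -0.5)
  expect_equal(choice_probabilities(st2, c("A", "B"))[["A"]],
               p[["A"]], tolerance = 1e-12)
  expect_equal(sum(p), 1)
  expect_error(choice_probabilities(st, c("A", "C")), "unknown stimulus")
})

test_that("side stickiness enters through the current side assignment", {
  spec <- model_spec(side_stickiness = TRUE)
  st <- agent_state(c("A", "B"))
  st$l["left"] <- 1
  p_A_left <- choice_probabilities(st, c("A", "B"),
                                   c(left = "A", right = "B"))
  p_A_right <- choice_probabilities(st, c("A", "B"),
                                    c(left = "B", right = "A"))
  expect_gt(p_A_left[["A"]], 0.5)
  expect_lt(p_A_right[["A"]], 0.5)
  expect_equal(p_A_left[["A"]], p_A_right[["B"]])
})

test_that("the learning update follows the delta rule and stickiness
           tracking", {
  spec <- model_spec(stim_stickiness = TRUE, side_stickiness = TRUE)
  pars <- param_set(tau = 0.5, tau_c = 0.5, d_c = 2, tau_l = 0.5, d_l = 1,
                    spec = spec)
  st <- agent_state(c("A", "B"))
  st <- update_state(st, "A", "left", "reward", pars, spec)
  expect_equal(st$v[["A"]], 0.5)     # one-step delta rule, r = +1
  expect_equal(st$v[["B"]], 0)
  expect_equal(st$c[["A"]], 1.0)     # tau_c * d_c
  st <- update_state(st, "A", "left", "reward", pars, spec)
  expect_equal(st$c[["A"]], 1.5)     # geometric approach to d_c = 2
  for (i in 1:50) st <- update_state(st, "A", "left", "reward", pars, spec)
  expect_equal(st$c[["A"]], 2, tolerance = 1e-9)
  expect_equal(st$l[["left"]], 1, tolerance = 1e-9)
  # punishment drives v toward -1
  st2 <- agent_state(c("A", "B"))
  st2 <- update_state(st2, "A", "left", "punish", pars, spec)
  expect_equal(st2$v[["A"]], -0.5)
  # zero rates are a fixed point
  spec0 <- model_spec()
  st3 <- update_state(agent_state(c("A", "B")), "A", "left", "reward",
                      param_set(tau = 0, spec = spec0), spec0)
  expect_equal(st3$v, c(A = 0, B = 0))
  # split valence uses the punishment rate on punish trials
  specv <- model_spec(split_valence = TRUE)
  st4 <- update_state(agent_state(c("A", "B")), "A", "left", "punish",
                      param_set(tau_r = 0.9, tau_p = 0.1, spec = specv),
                      specv)
  expect_equal(st4$v[["A"]], -0.1)
})

test_that("session log-likelihood matches the independent oracle for all
           eight specs", {
  trials <- ten_trial_log()
  for (spec in model_family()) {
    pars <- pars_for(spec)
    expect_equal(session_loglik(trials, pars, spec),
                 oracle_loglik(trials, full_pars, spec$split_valence,
                               spec$stim_stickiness, spec$side_stickiness),
                 tolerance = 1e-10, info = spec_label(spec))
  }
})

test_that("log-likelihood basics: indifference, additivity, corruption", {
  spec <- model_spec()
  trials <- ten_trial_log()
  expect_equal(session_loglik(trials, param_set(tau = 0, spec = spec),
                              spec), 10 * log(0.5))
  # duplicating the log as a second stage with a fresh stimulus pair
  # doubles the LL exactly: v (and c) reset at the new pair, and with no
  # side stickiness nothing else carries over
  pars <- param_set(tau = 0.4, spec = spec)
  t2 <- trials
  t2$stage <- "D6"
  for (col in c("stim_left", "stim_right", "correct_stim", "choice_stim"))
    t2[[col]] <- chartr("AB", "CD", t2[[col]])
  both <- rbind(trials, t2)
  expect_equal(session_loglik(both, pars, spec),
               2 * session_loglik(trials, pars, spec), tolerance = 1e-12)
  # corrupting one choice to the lower-probability option lowers the LL
  sim <- simulate_stage(pars, spec, stage_config("D5", max_sessions = 2,
                                                 criterion = 1))
  enc <- pvdrl:::encode_subject(as.data.frame(sim))
  probs <- pvdrl:::rl_probs_cpp(enc$chosen, enc$side1, enc$reinf,
                                enc$reset, pvdrl:::par6(pars, spec),
                                FALSE, FALSE)
  ll <- session_loglik(sim, pars, spec)
  i <- which(probs[cbind(seq_len(nrow(sim)), enc$chosen)] > 0.6)[1]
  skip_if(is.na(i))
  bad <- as.data.frame(sim)
  flip <- ifelse(bad$choice_stim[i] == bad$stim_left[i], bad$stim_right[i],
                 bad$stim_left[i])
  bad$choice_stim[i] <- flip
  bad$choice_side[i] <- ifelse(bad$choice_stim[i] == bad$stim_left[i],
                               "left", "right")
  expect_lt(session_loglik(bad, pars, spec), ll)
})

test_that("split-valence model with equal rates nests the single-rate
           model", {
  trials <- ten_trial_log()
  s1 <- model_spec(stim_stickiness = TRUE)
  s2 <- model_spec(split_valence = TRUE, stim_stickiness = TRUE)
  p1 <- param_set(tau = 0.37, tau_c = 0.2, d_c = 0.9, spec = s1)
  p2 <- param_set(tau_r = 0.37, tau_p = 0.37, tau_c = 0.2, d_c = 0.9,
                  spec = s2)
  expect_equal(session_loglik(trials, p1, s1),
               session_loglik(trials, p2, s2), tolerance = 1e-12)
})

test_that("compiled and reference likelihoods agree on simulated data", {
  set.seed(42)
  for (spec in model_family()) {
    pars <- pars_for(spec)
    sim <- simulate_stage(pars, spec,
                          stage_config("D5", max_sessions = 3,
                                       criterion = 1))
    enc <- pvdrl:::encode_subject(as.data.frame(sim))
    expect_equal(session_loglik(sim, pars, spec),
                 pvdrl:::loglik_encoded(enc, pars, spec),
                 tolerance = 1e-12, info = spec_label(spec))
  }
})

test_that("state stays within its bounds for arbitrary trial sequences", {
  spec <- model_spec(stim_stickiness = TRUE, side_stickiness = TRUE)
  set.seed(7)
  for (rep in 1:20) {
    pars <- param_set(tau = runif(1), tau_c = runif(1),
                      d_c = runif(1, 0, 3), tau_l = runif(1),
                      d_l = runif(1, 0, 3), spec = spec)
    st <- agent_state(c("A", "B"))
    for (t in 1:60) {
      st <- update_state(st, sample(c("A", "B"), 1),
                         sample(c("left", "right"), 1),
                         sample(c("reward", "punish"), 1), pars, spec)
      expect_true(all(abs(st$v) <= 1))
      expect_true(all(st$c >= 0 & st$c <= pars[["d_c"]] + 1e-12))
      expect_true(all(st$l >= 0 & st$l <= pars[["d_l"]] + 1e-12))
    }
  }
})
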