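test_that("probabilistic outcomes follow the valid-reinforcement rule", {
  set.seed(1)
  # degenerate probability: feedback always congruent
  oc <- assign_outcome(rep(TRUE, 50), 1.0)
  expect_true(all(oc$outcome == "reward") && all(oc$veracity))
  oc <- assign_outcome(rep(FALSE, 50), 1.0)
  expect_true(all(oc$outcome == "punish") && all(oc$veracity))
  expect_error(assign_outcome(TRUE, 0.3), "p_valid")
  expect_error(assign_outcome(TRUE, 1.2), "p_valid")
  # binomial convergence: reward fraction 0.8 within 4 SE at 1e5 draws
  oc <- assign_outcome(rep(TRUE, 1e5), 0.8)
  se <- sqrt(0.8 * 0.2 / 1e5)
  expect_lt(abs(mean(oc$outcome == "reward") - 0.8), 4 * se)
  expect_true(all(oc$veracity == (oc$outcome == "reward")))
})

test_that("a session has the configured length, balanced sides and valid
           records", {
  spec <- model_spec()
  pars <- param_set(tau = 0.3, spec = spec)
  cfg <- stage_config("D5", trials_per_session = 40)
  set.seed(2)
  out <- simulate_session(agent_state(c("D5_A", "D5_B")), pars, spec, cfg)
  tr <- out$trials
  expect_equal(nrow(tr), 40L)
  expect_equal(sum(tr$stim_left == "D5_A"), 20L)  # exact balance
  expect_true(all(tr$choice_stim == ifelse(tr$choice_side == "left",
                                           tr$stim_left, tr$stim_right)))
  expect_true(all(tr$veracity ==
                    ((tr$outcome == "reward") ==
                       (tr$choice_stim == tr$correct_stim))))
  expect_error(simulate_session(agent_state(c("X", "Y")), pars, spec, cfg),
               "different stimulus pair")
})

test_that("an indifferent agent chooses at chance and a saturated agent is
           near-perfect", {
  spec <- model_spec()
  cfg <- stage_config("D5", trials_per_session = 40)
  set.seed(3)
  st <- agent_state(c("D5_A", "D5_B"))
  correct <- 0
  for (i in 1:250) {  # 1e4 trials
    out <- simulate_session(st, param_set(tau = 0, spec = spec), spec, cfg)
    correct <- correct + sum(out$trials$choice_stim == "D5_A")
  }
  expect_lt(abs(correct / 1e4 - 0.5), 0.015)
  st$v <- c(D5_A = 20, D5_B = -20) # softmax saturation
  out <- simulate_session(st, param_set(tau = 0, spec = spec), spec, cfg)
  expect_true(all(out$trials$choice_stim == "D5_A"))
})

test_that("expected accuracy rises across session quintiles while
           learning", {
  spec <- model_spec()
  pars <- param_set(tau = 0.4, spec = spec)
  cfg <- stage_config("Q", trials_per_session = 30)
  set.seed(4)
  acc <- matrix(0, 1000, 30)
  for (i in 1:1000) {
    out <- simulate_session(agent_state(c("Q_A", "Q_B")), pars, spec, cfg)
    acc[i, ] <- out$trials$choice_stim == "Q_A"
  }
  q <- vapply(split(1:30, rep(1:5, each = 6)),
              function(ix) mean(acc[, ix]), numeric(1))
  expect_true(all(diff(q) > -0.01))
  expect_gt(q[5], q[1] + 0.05)
})

test_that("scripted policies terminate stages as expected", {
  cfg <- stage_config("D5", p_valid = 1, trials_per_session = 30,
                      max_sessions = 20)
  set.seed(5)
  st <- simulate_stage(cfg = cfg, policy = "always_correct")
  expect_equal(attr(st, "n_sessions"), 1L)
  expect_true(attr(st, "attained"))
  st <- simulate_stage(cfg = cfg, policy = "always_incorrect")
  expect_equal(attr(st, "n_sessions"), 20L)
  expect_false(attr(st, "attained"))
  # an indifferent agent essentially never reaches 27/30 correct
  # (binomial tail P(X >= 27 | n=30, p=0.5) ~ 2e-5)
  cfg2 <- stage_config("D5", trials_per_session = 30, criterion = 0.9,
                       max_sessions = 50)
  st <- simulate_stage(cfg = cfg2, policy = "random")
  expect_equal(attr(st, "n_sessions"), 50L)
  expect_false(attr(st, "attained"))
})

test_that("stage configuration rejects invalid values", {
  expect_error(stage_config("D5", p_valid = 0.4), "p_valid")
  expect_error(stage_config("D5", trials_per_session = 39), "even")
  expect_error(stage_config("D5", criterion = 0), "criterion")
  expect_error(stage_config("D5", max_sessions = 0), "max_sessions")
})

test_that("cohort simulation is reproducible and complete", {
  spec <- model_spec(stim_stickiness = TRUE)
  stages <- list(stage_config("D5", max_sessions = 3, criterion = 1,
                              trials_per_session = 20),
                 stage_config("D6", max_sessions = 3, criterion = 1,
                              trials_per_session = 20))
  plan <- simulation_plan(
    groups = list(a = param_set(tau = 0.3, tau_c = 0.2, d_c = 0.5,
                                spec = spec),
                  b = param_set(tau = 0.1, tau_c = 0.2, d_c = 0.5,
                                spec = spec),
                  c = param_set(tau = 0.5, tau_c = 0.2, d_c = 0.5,
                                spec = spec)),
    subjects_per_group = 4, stages = stages, spec = spec, seed = 99)
  coh1 <- simulate_cohort(plan)
  coh2 <- simulate_cohort(plan)
  expect_identical(as.data.frame(coh1), as.data.frame(coh2))
  blocks <- unique(coh1[, c("subject", "stage")])
  expect_equal(nrow(blocks), 3 * 4 * 2)  # groups x subjects x stages
  expect_equal(length(unique(coh1$subject)), 12L)
  expect_error(
    simulation_plan(groups = list(a = 1, a = 2), subjects_per_group = 1,
                    stages = stages, spec = spec, seed = 1),
    "uniquely named")
})

test_that("group-level distributions draw truncated-normal subject
           parameters", {
  spec <- model_spec()
  tiny <- stage_config("T", trials_per_session = 2, max_sessions = 1)
  plan <- simulation_plan(
    groups = list(g = list(mean = c(tau = 0.4), sd = c(tau = 0.05))),
    subjects_per_group = 1000, stages = list(tiny), spec = spec,
    seed = 123)
  coh <- simulate_cohort(plan)
  taus <- vapply(attr(coh, "params"), `[[`, numeric(1), "tau")
  expect_lt(abs(mean(taus) - 0.4), 0.01)  # truncation effect negligible
  expect_true(all(taus >= 0 & taus <= 1))
})

test_that("reversal stages flip the contingency and keep the stimulus
           pair", {
  spec <- model_spec()
  stages <- list(stage_config("D8", max_sessions = 2, criterion = 1,
                              trials_per_session = 10),
                 stage_config("D8R1", reversal_of = "D8",
                              max_sessions = 2, criterion = 1,
                              trials_per_session = 10),
                 stage_config("D8R2", reversal_of = "D8R1",
                              max_sessions = 2, criterion = 1,
                              trials_per_session = 10))
  plan <- simulation_plan(groups = list(g = c(tau = 0.3)),
                          subjects_per_group = 1, stages = stages,
                          spec = spec, seed = 5)
  coh <- simulate_cohort(plan)
  base <- coh[coh$stage == "D8", ]
  rev1 <- coh[coh$stage == "D8R1", ]
  rev2 <- coh[coh$stage == "D8R2", ]
  expect_equal(sort(unique(c(rev1$stim_left, rev1$stim_right))),
               sort(unique(c(base$stim_left, base$stim_right))))
  expect_true(unique(rev1$correct_stim) != unique(base$correct_stim))
  expect_equal(unique(rev2$correct_stim), unique(base$correct_stim))
})

test_that("trial logs round-trip through the text format", {
  spec <- model_spec()
  set.seed(8)
  st <- as.data.frame(simulate_stage(param_set(tau = 0.3, spec = spec),
                                     spec,
                                     stage_config("D5", max_sessions = 2,
                                                  criterion = 1)))
  path <- tempfile(fileext = ".tsv")
  log_path <- tempfile(fileext = ".log")
  write_trial_log(st, path, run_log = log_path)
  back <- read_trial_log(path)
  expect_equal(back, st, ignore_attr = TRUE)
  expect_equal(readLines(path, n = 1),
               paste(pvdrl:::trial_columns, collapse = "\t"))
  expect_true(grepl("true|false", readLines(path)[2]))
  expect_true(file.exists(log_path) && length(readLines(log_path)) == 1L)
})
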