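trial_rec <- function(choice, outcome, stim = (outcome == "CS+")) {
  list(choice = choice, outcome = outcome, stim_collected = stim)
}

test_that("single-trial Q updates obey the stated limiting cases", {
  p <- rl_params_q(0.24, 0.3, 0.2, 2, 1, 0)
  st <- update_qlearning(agent_state(), trial_rec("R", "CS+"), p)
  expect_equal(unname(st$q_rew["R"]), 0.24)
  expect_equal(unname(st$q_rew["L"]), 0)

  # zero forgetting leaves the unchosen value untouched
  p0 <- rl_params_q(0.5, 0.3, 0, 2, 1, 0)
  st <- agent_state(); st$q_rew[] <- c(0.6, 0.4)
  st2 <- update_qlearning(st, trial_rec("R", "CS-"), p0)
  expect_equal(unname(st2$q_rew["L"]), 0.6)

  # learning rate 1 jumps to the target in one step
  p1 <- rl_params_q(1, 0.3, 0.2, 2, 1, 0)
  st3 <- update_qlearning(st, trial_rec("L", "CS+"), p1)
  expect_equal(unname(st3$q_rew["L"]), 1)

  # no-choice trials leave the state unchanged
  expect_identical(update_qlearning(st, trial_rec(NA, "CS-"), p), st)

  # stimulation-as-RPE semantics: collected adds alpha, uncollected decays
  pr <- rl_params_q(0.5, 0.3, 0, 2, 1, 0, reward_semantics = "stim_as_rpe")
  st4 <- update_qlearning(st, trial_rec("R", "CS+", stim = TRUE), pr)
  expect_equal(unname(st4$q_rew["R"]), 0.4 + 0.5)
  st5 <- update_qlearning(st, trial_rec("R", "CS+", stim = FALSE), pr)
  expect_equal(unname(st5$q_rew["R"]), 0.2)
})

test_that("policy-family updates match their closed forms", {
  # actor-critic: first rewarded trial forces delta = 1, V = alpha_critic
  p <- rl_params_policy(0.2, 0.3, 2, 1, 0, alpha_critic = 0.4,
                        family = "actor_critic")
  st <- update_policy(agent_state(), trial_rec("R", "CS+"), p)
  expect_equal(st$v, 0.4)
  expect_equal(st$pi, 0.8 * 0 + 1 * 2 * 0.5 * 1)

  # REINFORCE with zero weights decays pi geometrically toward 0
  p0 <- rl_params_policy(0.25, 0.25, 0, 0, 0)
  st <- agent_state(); st$pi <- 1
  for (i in 1:5) st <- update_policy(st, trial_rec("R", "CS+"), p0)
  expect_equal(st$pi, 0.75^5)
})

test_that("choice probabilities come from the sigmoid decision rule", {
  p <- rl_params_q(0.3, 0.3, 0.1, 2, 0, 0)
  expect_equal(choice_probability(agent_state(), p), 0.5)
  st <- agent_state(); st$q_rew[] <- c(0, 1)        # dQ_rew = 1
  expect_equal(choice_probability(st, p), plogis(2), tolerance = 1e-12)
  # binary normalization holds for arbitrary states
  st$q_stay[] <- c(0.7, 0.1)
  p2 <- rl_params_q(0.3, 0.3, 0.1, 2, 1.5, -0.4)
  expect_equal(choice_probability(st, p2) +
                 (1 - choice_probability(st, p2)), 1)
  pp <- rl_params_policy(0.2, 0.2, 1, 1, 0.3)
  stp <- agent_state(); stp$pi <- 0.9
  expect_equal(choice_probability(stp, pp), plogis(0.3 + 0.9))
})

test_that("compiled trajectories equal straight single-step R loops to 1e-12", {
  s <- simulate_session(task_config(collection_prob = 0.6), agent_wsls(),
                        200, seed = 21)
  qp <- rl_params_q(0.35, 0.25, 0.15, 3, 1.2, 0.1)
  for (model in c("q_cs", "q_rpe")) {
    pars <- if (model == "q_rpe") {
      rl_params_q(0.35, 0.25, 0.15, 3, 1.2, 0.1, "stim_as_rpe")
    } else qp
    vals <- extract_decision_variables(s, pars, model)
    st <- agent_state()
    for (t in seq_len(nrow(s$trials))) {
      expect_equal(unname(st$q_rew), c(vals$qrew_l[t], vals$qrew_r[t]),
                   tolerance = 1e-12)
      expect_equal(unname(st$q_stay), c(vals$qstay_l[t], vals$qstay_r[t]),
                   tolerance = 1e-12)
      expect_equal(choice_probability(st, pars), vals$p_right[t],
                   tolerance = 1e-12)
      st <- update_qlearning(st, as.list(s$trials[t, ]), pars)
    }
  }
  for (fam in c("reinforce", "actor_critic")) {
    pars <- rl_params_policy(0.3, 0.2, 2, 1, -0.2,
                             alpha_critic = if (fam == "actor_critic") 0.4,
                             family = fam)
    vals <- extract_decision_variables(s, pars, fam)
    st <- agent_state()
    for (t in seq_len(nrow(s$trials))) {
      expect_equal(st$pi, vals$pi[t], tolerance = 1e-12)
      if (fam == "actor_critic")
        expect_equal(st$v, vals$v[t], tolerance = 1e-12)
      st <- update_policy(st, as.list(s$trials[t, ]), pars)
    }
  }
})

test_that("the conditioned-reinforcer variant and the literal stay update are honored", {
  s <- simulate_session(task_config(collection_prob = 0.5), agent_wsls(),
                        150, seed = 31)
  kp <- kappa_params(rl_params_q(0.4, 0.3, 0.2, 3, 1, 0), kappa = 0.6)
  vals <- extract_decision_variables(s, kp, "kappa")
  st <- agent_state()
  for (t in seq_len(nrow(s$trials))) {
    expect_equal(unname(st$q_rew), c(vals$qrew_l[t], vals$qrew_r[t]),
                 tolerance = 1e-12)
    st <- update_qlearning(st, as.list(s$trials[t, ]), kp)
  }
  # literal printed form of the unchosen stay update differs once values grow
  p <- rl_params_q(0.4, 0.3, 0.2, 3, 1, 0)
  st <- agent_state(); st$q_rew[] <- c(0.5, 0.5); st$q_stay[] <- c(0.5, 0.5)
  lit <- update_qlearning(st, trial_rec("R", "CS+"), p, literal_eq5 = TRUE)
  std <- update_qlearning(st, trial_rec("R", "CS+"), p)
  expect_equal(unname(lit$q_stay["L"]), 0.5 - 0.3 * (0.5 * 0.8))
  expect_equal(unname(std$q_stay["L"]), 0.5 - 0.3 * 0.5)
})

test_that("value ranges respect the models' structural bounds", {
  s <- simulate_session(task_config(), agent_wsls(), 400, seed = 41)
  v1 <- extract_decision_variables(s, rl_params_q(0.7, 0.6, 0.4, 3, 1, 0),
                                   "q_cs")
  expect_true(all(v1[, c("qrew_l", "qrew_r", "qstay_l", "qstay_r")] >= 0))
  expect_true(all(v1[, c("qrew_l", "qrew_r", "qstay_l", "qstay_r")] <= 1))
  expect_true(all(v1$v >= 0 & v1$v <= 1))
  # stimulation-as-RPE values are unbounded above: force an always-rewarded run
  s2 <- simulate_session(task_config(p_high = 1, p_low = 0.99),
                         agent_random(1), 200, seed = 5)
  v2 <- extract_decision_variables(
    s2, rl_params_q(0.5, 0.3, 0, 3, 1, 0, "stim_as_rpe"), "q_rpe")
  expect_gt(max(v2$qrew_r), 1)
})

test_that("decision-variable extraction is pre-update, deterministic, and side-consistent", {
  s <- simulate_session(task_config(), agent_wsls(), 120, seed = 51)
  p <- default_q_params()
  v1 <- extract_decision_variables(s, p, "q_cs")
  expect_true(all(v1[1, c("q_l", "q_r", "v", "dq", "dq_rl")] == 0))
  expect_identical(v1, extract_decision_variables(s, p, "q_cs"))
  # left hemisphere: contra is Right
  expect_identical(v1$q_contra, v1$q_r)
  expect_identical(v1$qrew_ipsi, v1$qrew_l)
  s_r <- s; s_r$hemisphere <- "right"
  v2 <- extract_decision_variables(s_r, p, "q_cs")
  expect_identical(v2$q_contra, v1$q_ipsi)
  expect_identical(v2$q_ipsi, v1$q_contra)
  expect_equal(v2$dq, -v1$dq)
  # composite values follow the weighted combination rule
  expect_equal(v1$q_r, p$beta_rew * v1$qrew_r + p$beta_stay * v1$qstay_r)
  # state-value trace follows its prediction-error recursion
  v_manual <- 0
  for (t in seq_len(nrow(s$trials))) {
    expect_equal(v1$v[t], v_manual, tolerance = 1e-12)
    if (!is.na(s$trials$choice[t]))
      v_manual <- v_manual + p$alpha_rew * (s$trials$r[t] - v_manual)
  }
  s_bad <- s; s_bad$trials$choice <- NA
  expect_error(extract_decision_variables(s_bad, p, "q_cs"), "completed")
})

test_that("detrending removes exactly the linear trial trend", {
  ramp <- 0.3 + 0.02 * (1:50)
  expect_equal(detrend_trial_variable(ramp), rep(0, 50),
               tolerance = 1e-12, ignore_attr = TRUE)
  expect_equal(detrend_trial_variable(rep(2, 30)), rep(0, 30))
  y <- withr::with_seed(3, 0.5 * (1:80) + rnorm(80))
  r <- detrend_trial_variable(y)
  expect_lt(abs(mean(r)), 1e-10)
  expect_lt(abs(cor(r, 1:80)), 1e-10)
  # closed-form OLS oracle
  x <- 1:80
  b <- cov(x, y) / var(x); a <- mean(y) - b * mean(x)
  expect_equal(as.numeric(r), y - (a + b * x), tolerance = 1e-10)
  expect_error(detrend_trial_variable(c(1, 2)), "3 trials")
})

test_that("on-policy simulation reproduces the win-stay calibration signatures", {
  cfg <- task_config()
  # a policy that ignores values repeats at chance
  flat <- simulate_on_policy(rl_params_q(0.4, 0.3, 0.2, 0, 0, 0), "q_cs",
                             cfg, 3000, seed = 61)
  expect_lt(abs(flat$summary$p_stay_csplus - 0.5), 0.05)
  expect_lt(abs(flat$summary$p_stay_csminus - 0.5), 0.05)
  # value-guided policy: repeat more after reward than after its absence
  sim <- simulate_on_policy(default_q_params(), "q_cs", cfg, 3000, seed = 62)
  expect_gt(sim$summary$p_stay_csplus, sim$summary$p_stay_csminus + 0.05)
  # choice probability rises across relative-value deciles
  dec <- sim$summary$p_right_by_dq_decile
  expect_gt(cor(dec, seq_along(dec)), 0.9)
  # after a reversal the new high side is acquired
  curve <- sim$summary$p_high_after_switch
  expect_gt(mean(tail(curve, 5)), mean(head(curve, 2)))
})
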