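test_that("session log-likelihood matches direct computation and chance level", {
  s <- simulate_session(task_config(), agent_wsls(), 150, seed = 71)
  p <- default_q_params()
  ll <- session_log_likelihood(s, p, "q_cs")
  vals <- extract_decision_variables(s, p, "q_cs")
  obs_r <- s$trials$choice == "R"
  manual <- sum(log(ifelse(obs_r, vals$p_right, 1 - vals$p_right)))
  expect_equal(ll$total, manual, tolerance = 1e-10)
  expect_equal(ll$per_choice, manual / 150, tolerance = 1e-10)
  # a value-blind policy scores exactly at chance
  flat <- session_log_likelihood(s, rl_params_q(0.3, 0.3, 0.1, 0, 0, 0),
                                 "q_cs")
  expect_equal(flat$per_choice, log(0.5))
  expect_equal(flat$accuracy, 0.5)   # all ties counted half
  s_bad <- s; s_bad$trials$choice <- NA
  expect_error(session_log_likelihood(s_bad, p, "q_cs"), "completed")
})

test_that("the likelihood is invariant to relabeling sides and negating bias", {
  s <- simulate_session(task_config(), agent_wsls(), 200, seed = 72)
  p <- rl_params_q(0.4, 0.3, 0.2, 3, 1, 0.5)
  s_flip <- s
  s_flip$trials$choice <- c(R = "L", L = "R")[s$trials$choice]
  s_flip$trials$block_side <- c(R = "L", L = "R")[s$trials$block_side]
  p_flip <- rl_params_q(0.4, 0.3, 0.2, 3, 1, -0.5)
  expect_equal(session_log_likelihood(s, p, "q_cs")$total,
               session_log_likelihood(s_flip, p_flip, "q_cs")$total,
               tolerance = 1e-10)
})

test_that("MAP fitting shrinks unidentifiable parameters and stays in range", {
  sim <- simulate_on_policy(rl_params_q(0.4, 0.3, 0.2, 0, 0, 0), "q_cs",
                            task_config(), 400, seed = 73)
  fit <- fit_session_map(sim$session, "q_cs", n_restarts = 6, seed = 1)
  expect_lt(abs(fit$params[["bias"]]), 0.2)
  expect_lt(abs(fit$ll_per_choice - log(0.5)), 0.02)
  rates <- fit$params[c("alpha_rew", "alpha_stay", "gamma_forget")]
  expect_true(all(rates > 0 & rates < 1))
})

test_that("MAP recovery lands near a coarse grid-search likelihood oracle", {
  true <- c(alpha_rew = 0.3, alpha_stay = 0.3, gamma_forget = 0.2,
            beta_rew = 4, beta_stay = 1, bias = 0)
  sim <- simulate_on_policy(do.call(rl_params_q, as.list(true)), "q_cs",
                            task_config(), 1000, seed = 74)
  fit <- fit_session_map(sim$session, "q_cs", n_restarts = 8, seed = 2)
  # profile the likelihood over (alpha_rew, beta_rew) on a coarse grid with
  # the other parameters held at truth: the MAP should sit inside the
  # high-likelihood region of that oracle surface
  grid_a <- seq(0.1, 0.6, by = 0.05)
  grid_b <- seq(1, 7, by = 0.5)
  surf <- outer(grid_a, grid_b, Vectorize(function(a, b) {
    session_log_likelihood(sim$session,
                           rl_params_q(a, 0.3, 0.2, b, 1, 0), "q_cs")$total
  }))
  best <- which(surf == max(surf), arr.ind = TRUE)
  expect_lt(abs(fit$params[["alpha_rew"]] - grid_a[best[1]]), 0.1)
  expect_lt(abs(fit$params[["beta_rew"]] - grid_b[best[2]]), 1.5)
  expect_true(fit$converged)
})

test_that("model comparison scores perfect, chance, and fitted predictors sensibly", {
  sim <- simulate_on_policy(default_q_params(), "q_cs", task_config(),
                            300, seed = 75)
  tbl <- compare_models(list(sim$session), models = c("q_cs", "reinforce"),
                        n_restarts = 4, seed = 3)
  expect_identical(nrow(tbl), 2L)
  expect_true(all(tbl$accuracy >= 0 & tbl$accuracy <= 1))
  expect_true(all(tbl$ll_per_choice <= 0))
  # both families capture this behavior about equally well
  expect_lt(abs(diff(tbl$ll_per_choice)), 0.1)
})

test_that("the conditioned-reinforcer value separates its generative regimes", {
  cfg <- task_config(collection_prob = 0.55)
  # regime 1: uncollected CS+ reinforces exactly like collected (kappa = 1)
  sess1 <- lapply(1:3, function(i)
    simulate_on_policy(default_q_params(), "q_cs", cfg, 600,
                       seed = 80 + i)$session)
  k1 <- fit_csplus_value(sess1, seed = 1, n_restarts = 6)
  # regime 2: uncollected CS+ acts like a CS- (kappa = 0)
  gen0 <- kappa_params(default_q_params(), kappa = 0)
  sess0 <- lapply(1:3, function(i)
    simulate_session(cfg, agent_model(gen0), 600, seed = 90 + i))
  k0 <- fit_csplus_value(sess0, seed = 1, n_restarts = 6)
  expect_gt(mean(k1$kappa), 0.6)
  expect_lt(mean(k0$kappa), 0.4)
  expect_true(all(k1$n_uncollected >= 5))
  # sessions without enough uncollected trials are excluded, not errors
  full <- simulate_on_policy(default_q_params(), "q_cs",
                             task_config(collection_prob = 1), 200,
                             seed = 99)$session
  expect_warning(out <- fit_csplus_value(list(full), seed = 1), "minimum")
  expect_null(out)
})

test_that("hierarchical fitting pools sessions and produces usable diagnostics", {
  true <- default_q_params()
  sessions <- lapply(1:4, function(i)
    simulate_on_policy(true, "q_cs", task_config(), 250,
                       seed = 120 + i)$session)
  hf <- fit_hierarchical(sessions, subject = c(1, 1, 2, 2), "q_cs",
                         n_chains = 2, n_iter = 250, warmup = 100, seed = 5)
  expect_identical(nrow(hf$session_params), 4L)
  rates <- as.matrix(hf$session_params[, c("alpha_rew", "alpha_stay",
                                           "gamma_forget")])
  expect_true(all(rates > 0 & rates < 1))
  expect_true(all(is.finite(hf$rhat)))
  expect_gt(hf$accept, 0.05)
  expect_lt(hf$accept, 0.95)
  # partial pooling should land the session betas in the truth's vicinity
  expect_lt(abs(median(hf$session_params$beta_rew) - true$beta_rew), 2.5)
  # single-session, single-subject: hierarchical medians track the MAP fit
  hf1 <- fit_hierarchical(sessions[1], subject = 1, "q_cs",
                          n_chains = 2, n_iter = 250, warmup = 100, seed = 6)
  map1 <- fit_session_map(sessions[[1]], "q_cs", n_restarts = 6, seed = 7)
  ll_h <- session_log_likelihood(
    sessions[[1]], unlist(hf1$session_params[1, -(1:2)]), "q_cs")$per_choice
  expect_lt(abs(ll_h - map1$ll_per_choice), 0.05)
})
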