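# Shared fixtures built in code at test time.

# A compact encoding configuration for fast unit tests (short kernel
# windows, a thinner penalty grid); the package defaults are exercised by
# the acceptance suite.
small_encoding_config <- function() {
  encoding_config(
    spans = list(go = c(0, 0.3), move_l = c(-0.2, 0.2),
                 move_r = c(-0.2, 0.2), cs_plus = c(0, 0.4),
                 stim = c(0, 0.4), cs_minus = c(0, 0.4)),
    grid_pad = c(0.3, 0.5),
    lambda_grid = 10^seq(-5, 5, length.out = 41),
    history_n = 5, history_range = c(0.01, 0.2))
}

default_q_params <- function() rl_params_q(0.4, 0.3, 0.2, 4, 1, 0)

# behavioral session + timeline + design for encoding tests
make_encoding_fixture <- function(n_trials = 60, seed = 11,
                                  config = small_encoding_config()) {
  sim <- simulate_on_policy(default_q_params(), "q_cs", task_config(),
                            n_trials, seed = seed)
  tl <- build_event_timeline(sim$session, config)
  des <- build_design_matrix(tl)
  list(sim = sim, session = sim$session, values = sim$values,
       timeline = tl, design = des, config = config)
}

# pool of value series from independent sessions (for pseudosession nulls)
make_value_pool <- function(vars, n_sessions = 6, n_trials = 120,
                            seed = 101) {
  series <- lapply(seq_len(n_sessions), function(i) {
    sim <- simulate_on_policy(default_q_params(), "q_cs", task_config(),
                              n_trials, seed = seed + i)
    sim$values[, vars, drop = FALSE]
  })
  pseudosession_pool(series)
}

event_names <- c("go", "move_l", "move_r", "cs_plus", "stim", "cs_minus")
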