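test_that("debias rule matches exhaustive enumeration and its stated examples", {
  cfg <- task_config()
  expect_true(apply_debias_rule(c(rep("R", 7), rep("L", 3)), "R", cfg))
  expect_false(apply_debias_rule(c(rep("R", 6), rep("L", 4)), "R", cfg))
  # below the window the rule cannot fire
  expect_false(apply_debias_rule(rep("R", 9), "R", cfg))
  # all 2^10 windows against a brute-force count
  for (i in 0:1023) {
    bits <- as.integer(intToBits(i))[1:10]
    ch <- ifelse(bits == 1L, "R", "L")
    expect_identical(apply_debias_rule(ch, "R", cfg), sum(ch == "R") >= 7)
  }
})

test_that("block length draws are uniform on the configured range", {
  cfg <- task_config()
  draws <- withr::with_seed(42, replicate(10000, draw_block_length(cfg)))
  expect_gte(min(draws), 20)
  expect_lte(max(draws), 40)
  gof <- chisq.test(table(factor(draws, levels = 20:40)))
  expect_gt(gof$p.value, 0.01)
  cfg2 <- task_config(block_len_min = 25, block_len_max = 25)
  expect_true(all(replicate(50, draw_block_length(cfg2)) == 25))
})

test_that("reward outcomes follow the block structure probabilities", {
  cfg <- task_config()
  s <- simulate_session(cfg, agent_random(0.5), 6000, seed = 7)
  tr <- s$trials
  high <- tr$choice == tr$block_side
  p_hi <- mean(tr$r[high]); n_hi <- sum(high)
  p_lo <- mean(tr$r[!high]); n_lo <- sum(!high)
  # binomial 99% intervals around the configured probabilities
  expect_lt(abs(p_hi - 0.7), 2.58 * sqrt(0.7 * 0.3 / n_hi))
  expect_lt(abs(p_lo - 0.1), 2.58 * sqrt(0.1 * 0.9 / n_lo))
  # degenerate limit: guaranteed reward on the high side
  s1 <- simulate_session(task_config(p_high = 1, p_low = 0),
                         agent_high_side(), 200, seed = 1)
  expect_true(all(s1$trials$r == 1))
})

test_that("blocks reverse at boundaries and are constant between them", {
  s <- simulate_session(task_config(), agent_wsls(), 800, seed = 3)
  tr <- s$trials
  b <- s$block_boundaries
  sides <- tr$block_side[b]
  expect_true(all(sides[-1] != sides[-length(sides)]))
  for (i in seq_along(b)) {
    hi <- if (i < length(b)) b[i + 1] - 1L else nrow(tr)
    expect_length(unique(tr$block_side[b[i]:hi]), 1)
  }
  # every completed trial has exactly one outcome label
  expect_true(all(tr$outcome %in% c("CS+", "CS-")))
})

test_that("sessions are deterministic given the seed and match a straight-loop oracle", {
  cfg <- task_config()
  s1 <- simulate_session(cfg, agent_random(0.4), 300, seed = 9)
  s2 <- simulate_session(cfg, agent_random(0.4), 300, seed = 9)
  expect_identical(s1, s2)
  s3 <- simulate_session(cfg, agent_random(0.4), 300, seed = 10)
  expect_false(identical(s1$trials, s3$trials))

  # independent straight-loop reimplementation consuming the same RNG stream
  oracle <- withr::with_seed(9L, {
    n <- 300L
    side <- integer(n); choice <- integer(n); r <- integer(n)
    stim <- logical(n)
    cur <- if (runif(1) < 0.5) 0L else 1L
    len <- 20L + as.integer(floor(runif(1) * 21))
    start <- 1L; blk_ch <- character(0)
    for (t in 1:n) {
      if (t > start && (t - start) >= len && length(blk_ch) >= 10 &&
          sum(tail(blk_ch, 10) == (if (cur == 1L) "R" else "L")) >= 7) {
        cur <- 1L - cur
        len <- 20L + as.integer(floor(runif(1) * 21))
        start <- t; blk_ch <- character(0)
      }
      side[t] <- cur
      if (t > 1) runif(1)          # iti
      runif(1)                     # quiescent
      a <- if (runif(1) < 0.4) 1L else 0L
      choice[t] <- a
      runif(2)                     # movement latency + duration
      p <- if (a == cur) 0.7 else 0.1
      r[t] <- as.integer(runif(1) < p)
      if (r[t] == 1L) { stim[t] <- runif(1) < 1; runif(1) }  # collect + lick
      blk_ch <- c(blk_ch, if (a == 1L) "R" else "L")
    }
    list(side = side, choice = choice, r = r)
  })
  expect_identical(ifelse(s1$trials$block_side == "R", 1L, 0L), oracle$side)
  expect_identical(ifelse(s1$trials$choice == "R", 1L, 0L), oracle$choice)
  expect_identical(s1$trials$r, oracle$r)
})

test_that("timed-out trials and task variants behave as specified", {
  # agent that never responds on trial 5
  ag <- function(t, hist) if (t == 5L) NA else 0.5
  s <- simulate_session(task_config(), ag, 20, seed = 2)
  expect_true(is.na(s$trials$choice[5]))
  expect_identical(s$trials$outcome[5], "CS-")
  expect_true(is.na(s$trials$t_move[5]))

  s_nl <- simulate_session(task_config(variant = "no_lick_with_cs"),
                           agent_random(), 300, seed = 4)
  tr <- s_nl$trials
  expect_identical(tr$stim_collected, tr$outcome == "CS+")
  expect_equal(tr$t_stim[tr$r == 1], tr$t_outcome[tr$r == 1])
  expect_true(s_nl$cs_present)

  s_no <- simulate_session(task_config(variant = "no_lick_without_cs"),
                           agent_random(), 50, seed = 4)
  expect_false(s_no$cs_present)
  # reward indicator is unchanged by removing the tone
  expect_true(any(s_no$trials$r == 1))
})

test_that("partial stimulation collection follows the collection probability", {
  s <- simulate_session(task_config(collection_prob = 0.5), agent_wsls(),
                        2000, seed = 6)
  tr <- s$trials
  rewarded <- tr$r == 1
  expect_true(all(!tr$stim_collected[!rewarded]))
  frac <- mean(tr$stim_collected[rewarded])
  expect_lt(abs(frac - 0.5), 2.58 * sqrt(0.25 / sum(rewarded)))
  # lick latency places stimulation inside the collection window
  lat <- tr$t_stim - tr$t_outcome
  expect_true(all(lat[!is.na(lat)] >= 0 & lat[!is.na(lat)] <= 1))
})
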