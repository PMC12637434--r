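#' Task configuration for the probabilistic reversal learning task
#'
#' Describes a two-alternative task in which one side pays reward (a CS+
#' followed by collectable brain stimulation) with high probability and the
#' other with low probability, and the high side reverses in blocks. Blocks
#' have a uniformly drawn default length but do not advance until a debiasing
#' criterion is met: the subject must have made at least `debias_required`
#' choices toward the high-probability side within the preceding
#' `debias_window` completed choices.
#'
#' @param p_high,p_low reward probabilities on the high / low side.
#' @param block_len_min,block_len_max bounds (trials) of the uniform default
#'   block length.
#' @param debias_required,debias_window debiasing rule: at least
#'   `debias_required` high-side choices within the last `debias_window`.
#' @param quiescent_range seconds of pre-trial wheel stillness (uniform draw).
#' @param choice_timeout seconds after the go cue before a trial times out.
#' @param lick_window seconds after the CS+ during which stimulation can be
#'   collected by licking.
#' @param collection_prob probability that the simulated agent collects the
#'   stimulation on a CS+ trial (the task variant may override this).
#' @param iti_range inter-trial interval range in seconds.
#' @param move_latency_range,move_duration_range seconds from go cue to
#'   movement onset, and movement duration, both uniform draws.
#' @param variant `"standard"` (lick required to collect stimulation),
#'   `"no_lick_with_cs"` (stimulation delivered automatically with the CS+),
#'   or `"no_lick_without_cs"` (as before, but the CS+ tone itself is omitted;
#'   rewards are unchanged).
#' @return A list of class `task_config`.
#' @export
task_config <- function(p_high = 0.7, p_low = 0.1,
                        block_len_min = 20L, block_len_max = 40L,
                        debias_required = 7L, debias_window = 10L,
                        quiescent_range = c(0.2, 0.5),
                        choice_timeout = 60,
                        lick_window = 1.0,
                        collection_prob = 1.0,
                        iti_range = c(4, 5),
                        move_latency_range = c(0.2, 0.6),
                        move_duration_range = c(0.15, 0.4),
                        variant = c("standard", "no_lick_with_cs",
                                    "no_lick_without_cs")) {
  variant <- match.arg(variant)
  stopf(p_low >= 0 && p_low < p_high && p_high <= 1,
        "need 0 <= p_low < p_high <= 1 (got p_low=%g, p_high=%g)", p_low, p_high)
  stopf(block_len_min <= block_len_max,
        "block_len_min must be <= block_len_max")
  stopf(debias_required <= debias_window,
        "debias_required must be <= debias_window")
  structure(list(
    p_high = p_high, p_low = p_low,
    block_len_min = as.integer(block_len_min),
    block_len_max = as.integer(block_len_max),
    debias_required = as.integer(debias_required),
    debias_window = as.integer(debias_window),
    quiescent_range = quiescent_range,
    choice_timeout = choice_timeout,
    lick_window = lick_window,
    collection_prob = collection_prob,
    iti_range = iti_range,
    move_latency_range = move_latency_range,
    move_duration_range = move_duration_range,
    variant = variant
  ), class = "task_config")
}

#' Draw a default block length
#'
#' Uniform over the integers `[block_len_min, block_len_max]`. Consumes one
#' draw from the current RNG stream.
#'
#' @param config a [task_config()].
#' @return integer block length.
#' @export
draw_block_length <- function(config) {
  lo <- config$block_len_min
  hi <- config$block_len_max
  lo + as.integer(floor(runif(1) * (hi - lo + 1L)))
}

#' Evaluate the block-advance debiasing rule
#'
#' A block may only advance once the subject has made at least
#' `debias_required` choices toward the high-probability side within the
#' preceding `debias_window` completed choices. Returns `FALSE` when fewer
#' than `debias_window` completed choices have occurred in the block, since
#' the window is undefined earlier.
#'
#' @param recent_choices character vector of completed choices (`"L"`/`"R"`)
#'   within the current block, oldest first.
#' @param block_side the current high-probability side, `"L"` or `"R"`.
#' @param config a [task_config()].
#' @return logical scalar.
#' @export
apply_debias_rule <- function(recent_choices, block_side, config) {
  w <- config$debias_window
  if (length(recent_choices) < w) return(FALSE)
  window <- tail(recent_choices, w)
  sum(window == block_side) >= config$debias_required
}

#' Simulate a session of the probabilistic reversal learning task
#'
#' Runs `n_trials` trials of the task under `config`, drawing choices from an
#' agent callback. Outcomes are Bernoulli draws at `p_high`/`p_low` depending
#' on whether the choice matches the current block's high-probability side.
#' The block flips side only once both the drawn default length is reached and
#' the debiasing rule holds. The whole session is driven by one seeded RNG
#' stream; per trial the draw order is: ITI (trials > 1), quiescent period,
#' choice, movement latency, movement duration, outcome, collection, lick
#' latency (conditional draws are simply skipped).
#'
#' @param config a [task_config()].
#' @param agent a function `(t, hist)` returning the probability of choosing
#'   Right on trial `t`, or `NA` for a timed-out (no-choice) trial. `hist` is
#'   an environment holding the vectors `choice` (0 = L, 1 = R, `NA` = none),
#'   `reward`, `stim`, `block_side` (0/1) filled up to trial `t - 1`, plus the
#'   current trial's `block_side` entry.
#' @param n_trials number of trials (>= 1).
#' @param seed integer seed; identical inputs give identical sessions.
#' @param hemisphere recording hemisphere used downstream for the
#'   contralateral/ipsilateral relabeling of choices and values.
#' @param session_id identifier stored with the session.
#' @return A list of class `session_data` with elements `trials` (data frame:
#'   `trial`, `block_side`, `choice`, `outcome`, `stim_collected`, `r`,
#'   `t_go`, `t_move`, `t_outcome`, `t_stim`), `block_boundaries` (first trial
#'   of each block), `hemisphere`, `cs_present`, `config`, `seed`.
#' @export
simulate_session <- function(config, agent, n_trials, seed,
                             hemisphere = c("left", "right"),
                             session_id = "sim") {
  hemisphere <- match.arg(hemisphere)
  stopf(is.function(agent), "`agent` must be a function")
  stopf(n_trials >= 1, "`n_trials` must be >= 1")
  withr::with_seed(as.integer(seed), {
    n <- as.integer(n_trials)
    choice <- integer(n); choice[] <- NA_integer_
    reward <- integer(n); stim <- integer(n)
    side <- integer(n)   # high-probability side, 0 = L, 1 = R
    t_go <- t_move <- t_outcome <- t_stim <- rep(NA_real_, n)

    hist <- new.env(parent = emptyenv())
    hist$choice <- choice; hist$reward <- reward
    hist$stim <- stim; hist$block_side <- side

    cur_side <- if (runif(1) < 0.5) 0L else 1L
    blk_len <- draw_block_length(config)
    blk_start <- 1L
    blk_choices <- character(0)   # completed choices within the block
    boundaries <- 1L
    clock <- 0

    no_lick <- config$variant != "standard"
    for (t in seq_len(n)) {
      if (t > blk_start && (t - blk_start) >= blk_len &&
          apply_debias_rule(blk_choices, if (cur_side == 1L) "R" else "L",
                            config)) {
        cur_side <- 1L - cur_side
        blk_len <- draw_block_length(config)
        blk_start <- t
        blk_choices <- character(0)
        boundaries <- c(boundaries, t)
      }
      side[t] <- cur_side
      hist$block_side <- side

      if (t > 1L) clock <- clock + runif(1, config$iti_range[1], config$iti_range[2])
      clock <- clock + runif(1, config$quiescent_range[1], config$quiescent_range[2])
      t_go[t] <- clock

      p_r <- agent(t, hist)
      if (is.na(p_r)) {
        # timed-out trial: no choice, CS- outcome, no debias contribution
        clock <- clock + config$choice_timeout
        t_outcome[t] <- clock
        reward[t] <- 0L
      } else {
        a <- if (runif(1) < p_r) 1L else 0L
        choice[t] <- a
        lat <- runif(1, config$move_latency_range[1], config$move_latency_range[2])
        dur <- runif(1, config$move_duration_range[1], config$move_duration_range[2])
        t_move[t] <- t_go[t] + lat
        clock <- t_move[t] + dur
        t_outcome[t] <- clock
        p_rew <- if (a == cur_side) config$p_high else config$p_low
        reward[t] <- as.integer(runif(1) < p_rew)
        if (reward[t] == 1L) {
          if (no_lick) {
            stim[t] <- 1L
            t_stim[t] <- t_outcome[t]
          } else if (runif(1) < config$collection_prob) {
            stim[t] <- 1L
            t_stim[t] <- t_outcome[t] + runif(1, 0, config$lick_window)
          }
        }
        blk_choices <- c(blk_choices, if (a == 1L) "R" else "L")
      }
      hist$choice <- choice; hist$reward <- reward; hist$stim <- stim
    }

    trials <- data.frame(
      trial = seq_len(n),
      block_side = ifelse(side == 1L, "R", "L"),
      choice = ifelse(is.na(choice), NA_character_,
                      ifelse(choice == 1L, "R", "L")),
      outcome = ifelse(reward == 1L, "CS+", "CS-"),
      stim_collected = stim == 1L,
      r = reward,
      t_go = t_go, t_move = t_move, t_outcome = t_outcome, t_stim = t_stim,
      stringsAsFactors = FALSE
    )
    structure(list(
      session_id = session_id,
      trials = trials,
      block_boundaries = boundaries,
      hemisphere = hemisphere,
      cs_present = config$variant != "no_lick_without_cs",
      config = config,
      seed = as.integer(seed)
    ), class = "session_data")
  })
}

#' @method print session_data
#' @export
print.session_data <- function(x, ...) {
  n <- nrow(x$trials)
  cat(sprintf(
    "<session_data '%s'> %d trials, %d blocks, %s hemisphere, %.1f%% rewarded\n",
    x$session_id, n, length(x$block_boundaries), x$hemisphere,
    100 * mean(x$trials$r)))
  invisible(x)
}

#' Built-in choice agents
#'
#' `agent_random()` picks Right with fixed probability; `agent_high_side()`
#' always picks the current high-probability side (an oracle used for
#' calibration checks); `agent_wsls()` is win-stay / lose-shift with a lapse
#' rate. Each returns a function suitable for [simulate_session()].
#'
#' @param p_right probability of a Right choice.
#' @param lapse probability of deviating from the win-stay/lose-shift rule.
#' @return an agent function `(t, hist) -> probability of Right`.
#' @export
agent_random <- function(p_right = 0.5) {
  function(t, hist) p_right
}

#' @rdname agent_random
#' @export
agent_high_side <- function() {
  function(t, hist) as.numeric(hist$block_side[t])
}

#' @rdname agent_random
#' @export
agent_wsls <- function(lapse = 0.05) {
  function(t, hist) {
    if (t == 1L) return(0.5)
    prev <- hist$choice[t - 1L]
    if (is.na(prev)) return(0.5)
    stay <- hist$reward[t - 1L] == 1L
    target <- if (stay) prev else 1L - prev
    if (target == 1L) 1 - lapse else lapse
  }
}
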