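.event_names <- c("go", "move_l", "move_r", "cs_plus", "stim", "cs_minus")

#' Build the event timeline of a session on the 10 ms grid
#'
#' Lays each analyzable trial (completed choice, all timestamps present) on
#' its own bin grid running from shortly before the go cue to shortly after
#' the outcome, records where each behavioral event falls (half-open bins,
#' left-aligned; event times snapped with ties toward the earlier bin), and
#' marks which bins are covered by at least one event's kernel window (the
#' coverage used for z-scoring). In the task variant without a CS+ tone,
#' rewarded trials carry a stimulation event but no CS+ indicator.
#'
#' @param session a `session_data`.
#' @param config an [encoding_config()].
#' @return list of class `event_timeline`: `events` (data frame: trial, row
#'   within included trials, event, time relative to go cue, global bin),
#'   `row_trial` (included-trial index per grid row), `bin_time` (bin start
#'   time relative to the go cue per row), `trial_rows` (list of row ranges),
#'   `coverage` (logical per row), `included` (logical per session trial),
#'   `trial_info` (block side / choice / outcome per included trial),
#'   `n_rows`, `config`.
#' @export
build_event_timeline <- function(session, config = encoding_config()) {
  tr <- session$trials
  b <- config$bin
  included <- !is.na(tr$choice) & is.finite(tr$t_go) & is.finite(tr$t_move) &
    is.finite(tr$t_outcome)
  idx <- which(included)
  stopf(length(idx) > 0, "no analyzable trials in session")

  n_per <- integer(length(idx))
  row_trial <- integer(0); bin_time <- numeric(0)
  trial_rows <- vector("list", length(idx))
  ev_rows <- list()
  offset <- 0L
  for (k in seq_along(idx)) {
    i <- idx[k]
    rel_start <- -config$grid_pad[1]
    last_ev <- max(tr$t_outcome[i],
                   if (isTRUE(tr$stim_collected[i])) tr$t_stim[i] else -Inf)
    rel_end <- (last_ev - tr$t_go[i]) + config$grid_pad[2]
    m <- as.integer(ceiling((rel_end - rel_start) / b))
    n_per[k] <- m
    trial_rows[[k]] <- c(offset + 1L, offset + m)
    row_trial <- c(row_trial, rep(k, m))
    bin_time <- c(bin_time, rel_start + (seq_len(m) - 1L) * b)

    ev <- list(go = 0, move = tr$t_move[i] - tr$t_go[i],
               out = tr$t_outcome[i] - tr$t_go[i])
    add_event <- function(name, t_rel) {
      loc <- as.integer(floor((t_rel - rel_start) / b)) + 1L
      if (loc >= 1L && loc <= m) {
        ev_rows[[length(ev_rows) + 1L]] <<- data.frame(
          trial = i, row = k, event = name, time = t_rel,
          bin = offset + loc, stringsAsFactors = FALSE)
      }
    }
    add_event("go", 0)
    add_event(if (tr$choice[i] == "L") "move_l" else "move_r", ev$move)
    if (tr$r[i] == 1L) {
      if (isTRUE(session$cs_present)) add_event("cs_plus", ev$out)
      if (isTRUE(tr$stim_collected[i]))
        add_event("stim", tr$t_stim[i] - tr$t_go[i])
    } else {
      add_event("cs_minus", ev$out)
    }
    offset <- offset + m
  }
  events <- do.call(rbind, ev_rows)

  coverage <- logical(offset)
  for (r in seq_len(nrow(events))) {
    sp <- config$spans[[events$event[r]]]
    lo <- events$bin[r] + as.integer(round(sp[1] / b))
    hi <- events$bin[r] + as.integer(round(sp[2] / b)) - 1L
    rng <- trial_rows[[events$row[r]]]
    lo <- max(lo, rng[1]); hi <- min(hi, rng[2])
    if (lo <= hi) coverage[lo:hi] <- TRUE
  }

  structure(list(
    events = events, row_trial = row_trial, bin_time = bin_time,
    trial_rows = trial_rows, coverage = coverage, included = included,
    trial_info = data.frame(trial = tr$trial[idx],
                            block_side = tr$block_side[idx],
                            choice = tr$choice[idx],
                            outcome = tr$outcome[idx],
                            stringsAsFactors = FALSE),
    n_rows = offset, config = config
  ), class = "event_timeline")
}

#' Z-score binned spiking over kernel-covered bins
#'
#' The mean and standard deviation are computed over bins covered by at
#' least one event kernel; all bins are then transformed with those two
#' numbers. Neurons with zero variance over covered bins are flagged
#' unusable rather than raising an error.
#'
#' @param counts numeric vector of binned activity on the timeline grid.
#' @param coverage logical coverage mask (from [build_event_timeline()]).
#' @return list: `z` (transformed series), `mu`, `sigma`, `usable`.
#' @export
zscore_binned_spikes <- function(counts, coverage) {
  stopf(length(counts) == length(coverage),
        "counts and coverage differ in length")
  stopf(sum(coverage) >= 2, "need at least 2 covered bins")
  mu <- mean(counts[coverage])
  sigma <- sd(counts[coverage])
  if (!is.finite(sigma) || sigma == 0) {
    return(list(z = rep(NA_real_, length(counts)), mu = mu, sigma = sigma,
                usable = FALSE))
  }
  list(z = (counts - mu) / sigma, mu = mu, sigma = sigma, usable = TRUE)
}

#' Build the event design matrix
#'
#' Convolves each event's binary indicator with its raised-cosine basis,
#' confined within each trial's grid, producing one sparse column per basis
#' function per event.
#'
#' @param timeline an [build_event_timeline()] result.
#' @param config an [encoding_config()] (defaults to the timeline's).
#' @return list of class `encoding_design`: `X` (sparse rows x columns),
#'   `col_map` (data frame: column, event, basis index), `blocks` (named
#'   list of column indices per event), `bases` (named list of `basis_set`),
#'   `timeline`.
#' @export
build_design_matrix <- function(timeline, config = timeline$config) {
  b <- config$bin
  bases <- lapply(.event_names, function(e)
    make_basis("linear_cosine", span = config$spans[[e]], bin = b,
               spacing = config$basis_spacing))
  names(bases) <- .event_names

  ii <- list(); jj <- list(); xx <- list()
  col_map <- list()
  col0 <- 0L
  blocks <- list()
  for (e in .event_names) {
    B <- bases[[e]]$matrix
    offs <- as.integer(round(config$spans[[e]][1] / b)) +
      seq_len(nrow(B)) - 1L
    nb <- ncol(B)
    blocks[[e]] <- col0 + seq_len(nb)
    trip <- which(B != 0, arr.ind = TRUE)
    ev <- timeline$events[timeline$events$event == e, , drop = FALSE]
    if (nrow(ev) > 0) {
      for (r in seq_len(nrow(ev))) {
        rows <- ev$bin[r] + offs[trip[, 1]]
        rng <- timeline$trial_rows[[ev$row[r]]]
        keep <- rows >= rng[1] & rows <= rng[2]
        ii[[length(ii) + 1L]] <- rows[keep]
        jj[[length(jj) + 1L]] <- col0 + trip[keep, 2]
        xx[[length(xx) + 1L]] <- B[trip[keep, , drop = FALSE]]
      }
    }
    col_map[[e]] <- data.frame(column = col0 + seq_len(nb), event = e,
                               basis = seq_len(nb), stringsAsFactors = FALSE)
    col0 <- col0 + nb
  }
  X <- Matrix::sparseMatrix(i = unlist(ii), j = unlist(jj), x = unlist(xx),
                            dims = c(timeline$n_rows, col0))
  structure(list(X = X, col_map = do.call(rbind, col_map), blocks = blocks,
                 bases = bases, timeline = timeline),
            class = "encoding_design")
}

# Spike-history predictors: each neuron's own z-scored activity convolved
# with the causal log-cosine basis, within trials, lagged >= 1 bin.
.history_design <- function(z, timeline, config) {
  H <- make_basis("log_cosine_history", bin = config$bin,
                  n = config$history_n, range = config$history_range)
  L <- nrow(H$matrix)
  n <- timeline$n_rows
  Xh <- matrix(0, n, config$history_n)
  for (rng in timeline$trial_rows) {
    seg <- z[rng[1]:rng[2]]
    m <- length(seg)
    lagged <- c(0, seg[-m])              # shift by one bin: strictly causal
    padded <- c(rep(0, L), lagged)
    for (j in seq_len(config$history_n)) {
      f <- stats::filter(padded, H$matrix[, j], sides = 1)
      Xh[rng[1]:rng[2], j] <- f[(L + 1):(L + m)]
    }
  }
  Xh
}

#' Stratified cross-validation folds over trials
#'
#' Assigns trials to folds while approximately balancing the composition of
#' block side, choice, and outcome across folds: trials are grouped into
#' strata by those three labels and dealt round-robin (shuffled within
#' stratum) into folds.
#'
#' @param trial_info data frame with `block_side`, `choice`, `outcome`.
#' @param k number of folds.
#' @param seed RNG seed.
#' @return integer fold id per trial.
#' @export
stratified_trial_folds <- function(trial_info, k = 5, seed = 1) {
  strata <- interaction(trial_info$block_side, trial_info$choice,
                        trial_info$outcome, drop = TRUE)
  fold <- integer(nrow(trial_info))
  withr::with_seed(as.integer(seed), {
    nxt <- 0L
    for (s in levels(strata)) {
      id <- sample(which(strata == s))
      fold[id] <- (nxt + seq_along(id) - 1L) %% k + 1L
      nxt <- (nxt + length(id)) %% k
    }
  })
  fold
}
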