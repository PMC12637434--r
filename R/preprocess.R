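#' Wheel movement-onset detection parameters
#'
#' @param coarse_thresh cm/s threshold on the 200 ms-averaged speed that
#'   defines candidate movement periods.
#' @param coarse_window seconds of the coarse moving average.
#' @param merge_gap merge adjacent movements separated by less than this
#'   (s).
#' @param min_duration discard movements shorter than this (s).
#' @param precise_thresh cm/s threshold on the 5 ms-averaged speed defining
#'   the precise onset.
#' @param precise_window seconds of the fine moving average.
#' @param search_pre seconds before the go cue from which a trial's movement
#'   onset may be taken.
#' @return list of class `wheel_onset_params`.
#' @export
wheel_onset_params <- function(coarse_thresh = 1, coarse_window = 0.2,
                               merge_gap = 0.1, min_duration = 0.05,
                               precise_thresh = 0.2, precise_window = 0.005,
                               search_pre = 0.2) {
  stopf(coarse_thresh > 0 && precise_thresh > 0, "thresholds must be > 0")
  structure(list(coarse_thresh = coarse_thresh, coarse_window = coarse_window,
                 merge_gap = merge_gap, min_duration = min_duration,
                 precise_thresh = precise_thresh,
                 precise_window = precise_window, search_pre = search_pre),
            class = "wheel_onset_params")
}

#' Detect wheel movement onsets
#'
#' Coarse movement periods are those whose 200 ms moving-average speed
#' reaches 1 cm/s; adjacent periods separated by under 100 ms are merged and
#' periods shorter than 50 ms dropped. Each movement's precise onset is the
#' first instant its 5 ms moving-average speed reaches 0.2 cm/s, found by
#' extending the coarse period backward while the fine speed stays above
#' that threshold. If a session is supplied, each trial is assigned the
#' first onset between 0.2 s before its go cue and its outcome; trials with
#' no onset in that window are flagged for exclusion.
#'
#' @param time,position uniformly sampled trace (s, cm), rate >= 200 Hz.
#' @param params a [wheel_onset_params()].
#' @param session optional `session_data` for per-trial assignment.
#' @return list: `onsets` (times of all detected movements), `trial_onsets`
#'   (per-trial onset time or `NA`, when `session` given).
#' @export
detect_wheel_onsets <- function(time, position,
                                params = wheel_onset_params(),
                                session = NULL) {
  dt <- diff(time)
  stopf(max(abs(dt - dt[1])) < 1e-9 * max(1, abs(dt[1])),
        "trace must be uniformly sampled")
  fs <- 1 / dt[1]
  stopf(fs >= 200, "sampling rate must be >= 200 Hz")
  speed <- c(0, abs(diff(position))) * fs
  k_coarse <- max(1L, round(params$coarse_window * fs))
  k_fine <- max(1L, round(params$precise_window * fs))
  coarse <- moving_average(speed, k_coarse)
  fine <- moving_average(speed, k_fine)

  runs <- rle(coarse >= params$coarse_thresh)
  ends <- cumsum(runs$lengths)
  starts <- ends - runs$lengths + 1L
  seg <- cbind(starts[runs$values], ends[runs$values])
  if (nrow(seg) > 0) {
    merged <- seg[1, , drop = FALSE]
    if (nrow(seg) > 1) {
      for (r in 2:nrow(seg)) {
        gap <- (seg[r, 1] - merged[nrow(merged), 2]) / fs
        if (gap < params$merge_gap) merged[nrow(merged), 2] <- seg[r, 2]
        else merged <- rbind(merged, seg[r, ])
      }
    }
    dur <- (merged[, 2] - merged[, 1] + 1L) / fs
    merged <- merged[dur >= params$min_duration, , drop = FALSE]
  } else merged <- seg

  onsets <- numeric(0)
  for (r in seq_len(nrow(merged))) {
    i <- merged[r, 1]
    while (i > 1L && fine[i - 1L] >= params$precise_thresh) i <- i - 1L
    while (i <= merged[r, 2] && fine[i] < params$precise_thresh) i <- i + 1L
    if (i <= merged[r, 2]) onsets <- c(onsets, time[i])
  }

  trial_onsets <- NULL
  if (!is.null(session)) {
    tr <- session$trials
    trial_onsets <- vapply(seq_len(nrow(tr)), function(i) {
      if (is.na(tr$choice[i])) return(NA_real_)
      lo <- tr$t_go[i] - params$search_pre
      hi <- tr$t_outcome[i]
      cand <- onsets[onsets >= lo & onsets <= hi]
      if (length(cand) == 0) NA_real_ else cand[1]
    }, numeric(1))
  }
  list(onsets = onsets, trial_onsets = trial_onsets)
}

#' Label each trial's choice as contralateral or ipsilateral
#'
#' On the left hemisphere contralateral choices are counterclockwise wheel
#' movements, i.e. Right choices; the right hemisphere is mirrored.
#'
#' @param session a `session_data`.
#' @param hemisphere `"left"` or `"right"` (defaults to the session's).
#' @return the session with a `laterality` column (`"contra"`, `"ipsi"`, or
#'   `NA` for no-choice trials) added to its trial table.
#' @export
assign_laterality <- function(session, hemisphere = session$hemisphere) {
  stopf(hemisphere %in% c("left", "right"), "unknown hemisphere")
  contra <- if (hemisphere == "left") "R" else "L"
  session$trials$laterality <- ifelse(is.na(session$trials$choice), NA,
                                      ifelse(session$trials$choice == contra,
                                             "contra", "ipsi"))
  session
}

#' Apply the standard trial exclusions
#'
#' Removes the first and last ten trials of the session, trials without a
#' completed choice, and trials whose wheel movement-onset time is missing.
#'
#' @param session a `session_data`.
#' @param n_edge trials trimmed from each end.
#' @return list: `session` (filtered copy), `log` (data frame of removed
#'   trials and reasons).
#' @export
apply_trial_exclusions <- function(session, n_edge = 10) {
  tr <- session$trials
  n <- nrow(tr)
  if (n <= 2 * n_edge) {
    warning("session has too few trials; all excluded")
    out <- session
    out$trials <- tr[0, ]
    return(list(session = out,
                log = data.frame(trial = tr$trial, reason = "edge")))
  }
  reason <- rep(NA_character_, n)
  reason[seq_len(n_edge)] <- "edge"
  reason[(n - n_edge + 1L):n] <- "edge"
  reason[is.na(reason) & is.na(tr$choice)] <- "no_choice"
  reason[is.na(reason) & !is.finite(tr$t_move)] <- "no_movement_onset"
  keep <- is.na(reason)
  out <- session
  out$trials <- tr[keep, , drop = FALSE]
  out$block_boundaries <- session$block_boundaries[
    session$block_boundaries %in% tr$trial[keep]]
  list(session = out,
       log = data.frame(trial = tr$trial[!keep], reason = reason[!keep]))
}
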