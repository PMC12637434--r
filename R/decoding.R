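#' Decoder settings
#'
#' Time-resolved population decoding of trial-by-trial values: activity is
#' re-binned into 100 ms intervals, a separate lasso decoder is trained per
#' time bin with 5-fold nested stratified cross-validation, and performance
#' is corrected by pseudosession nulls. Windows are aligned to the variable's
#' relevant event: state value from 0.5 s before to 2 s after the outcome,
#' relative value and the per-choice action values from 0.5 s before to
#' 0.5 s after the go cue. Confound-limiting trial filters: contralateral
#' choices only for relative value (and the matching choice for each action
#' value), rewarded trials only for state value; the decoded values are
#' always pre-update.
#'
#' @param bin decoding bin width (s).
#' @param group_sizes numbers of simultaneously recorded neurons per decoder.
#' @param repeats random neuron combinations per group size.
#' @param outer_folds,inner_folds nested stratified cross-validation.
#' @param lambda_grid lasso penalty grid (8 log-spaced decades by default).
#' @param windows,align per-variable decoding windows (s) and alignment
#'   events.
#' @param n_null pseudosession draws for the null correction (desk-scale
#'   default 20; the heavier published-style 200 is available by setting
#'   it).
#' @return list of class `decoder_spec`.
#' @export
decoder_spec <- function(bin = 0.1,
                         group_sizes = c(10, 20, 30, 40),
                         repeats = 100,
                         outer_folds = 5, inner_folds = 5,
                         lambda_grid = 10^seq(-6, 1, by = 1),
                         windows = list(v = c(-0.5, 2), dq = c(-0.5, 0.5),
                                        q_contra = c(-0.5, 0.5),
                                        q_ipsi = c(-0.5, 0.5)),
                         align = list(v = "outcome", dq = "go",
                                      q_contra = "go", q_ipsi = "go"),
                         n_null = 20) {
  structure(list(bin = bin, group_sizes = group_sizes, repeats = repeats,
                 outer_folds = outer_folds, inner_folds = inner_folds,
                 lambda_grid = lambda_grid, windows = windows, align = align,
                 n_null = n_null),
            class = "decoder_spec")
}

#' Stratified folds over continuous targets (Freedman-Diaconis rule)
#'
#' Trials are discretized into bins of uniform width `2 * IQR * n^(-1/3)`
#' based on the target value; bins with fewer trials than folds are merged
#' with their nearest neighbor; trials are shuffled within bins and dealt
#' round-robin so each fold receives a similar number from every bin. A zero
#' IQR collapses to a single stratum (plain shuffled folds).
#'
#' @param values numeric target per trial.
#' @param n_folds number of folds.
#' @param seed RNG seed.
#' @return integer fold assignment per trial.
#' @export
stratify_folds <- function(values, n_folds = 5, seed = 1) {
  n <- length(values)
  stopf(n >= n_folds, "need at least as many trials as folds")
  iqr <- IQR(values)
  width <- 2 * iqr * n^(-1 / 3)
  bins <- if (iqr == 0 || width <= 0) rep(1L, n) else {
    findInterval(values, seq(min(values), max(values) + width, by = width))
  }
  repeat {
    tab <- table(bins)
    small <- as.integer(names(tab)[tab < n_folds])
    if (length(small) == 0 || length(tab) == 1) break
    b <- small[1]
    others <- setdiff(as.integer(names(tab)), b)
    nb <- others[which.min(abs(others - b))]
    bins[bins == b] <- nb
  }
  fold <- integer(n)
  withr::with_seed(as.integer(seed), {
    nxt <- 0L
    for (b in unique(bins)) {
      id <- sample(which(bins == b))
      fold[id] <- (nxt + seq_along(id) - 1L) %% n_folds + 1L
      nxt <- (nxt + length(id)) %% n_folds
    }
  })
  fold
}

#' Nested stratified cross-validated lasso decoding
#'
#' Outer folds estimate performance; for each outer training set an inner
#' stratified cross-validation selects the lasso penalty by mean validation
#' mean-squared error over the grid, the decoder is refit on the whole outer
#' training set at the winning penalty, and scored on the held-out fold.
#' Held-out R2 uses the test fold's own variance and can be negative; it is
#' reported as-is.
#'
#' @param activity trials x neurons matrix for one time bin.
#' @param targets numeric target per trial.
#' @param spec a [decoder_spec()].
#' @param seed RNG seed.
#' @return mean held-out R2 across outer folds.
#' @export
nested_cv_decode <- function(activity, targets, spec = decoder_spec(),
                             seed = 1) {
  stopf(all(is.finite(targets)), "targets must be finite")
  stopf(nrow(activity) == length(targets),
        "activity rows must match targets")
  lam <- sort(spec$lambda_grid, decreasing = TRUE)
  outer <- stratify_folds(targets, spec$outer_folds, seed)
  r2s <- vapply(seq_len(spec$outer_folds), function(f) {
    tr <- outer != f
    y_tr <- targets[tr]; X_tr <- activity[tr, , drop = FALSE]
    inner <- stratify_folds(y_tr, spec$inner_folds, child_seed(seed, f))
    mse <- matrix(NA_real_, spec$inner_folds, length(lam))
    for (g in seq_len(spec$inner_folds)) {
      itr <- inner != g
      fit <- glmnet::glmnet(X_tr[itr, , drop = FALSE], y_tr[itr],
                            lambda = lam, alpha = 1)
      pred <- predict(fit, X_tr[!itr, , drop = FALSE], s = lam)
      mse[g, ] <- colMeans((y_tr[!itr] - pred)^2)
    }
    best <- lam[which.min(colMeans(mse))]
    fit <- glmnet::glmnet(X_tr, y_tr, lambda = lam, alpha = 1)
    pred <- as.numeric(predict(fit, activity[!tr, , drop = FALSE], s = best))
    y_te <- targets[!tr]
    1 - sum((y_te - pred)^2) / sum((y_te - mean(y_te))^2)
  }, numeric(1))
  mean(r2s)
}

#' Re-bin spiking activity around an alignment event
#'
#' Sums the 10 ms grid counts into decoding bins (100 ms by default) within
#' a window around the go cue or the outcome of each included trial.
#'
#' @param counts neurons x grid rows matrix (from [generate_population()] or
#'   a spike container).
#' @param timeline an [build_event_timeline()] result.
#' @param session the session (for outcome times).
#' @param align `"go"` or `"outcome"`.
#' @param window `c(from, to)` seconds around the alignment event.
#' @param bin decoding bin width (s).
#' @return array trials x neurons x time bins, with attribute `bin_start`
#'   (window-relative start time of each decoding bin).
#' @export
bin_activity <- function(counts, timeline, session, align = c("go", "outcome"),
                         window = c(-0.5, 0.5), bin = 0.1) {
  align <- match.arg(align)
  tr <- session$trials
  inc <- which(timeline$included)
  n_trial <- length(inc)
  starts <- seq(window[1], window[2] - bin / 2, by = bin)
  out <- array(0, c(n_trial, nrow(counts), length(starts)))
  for (k in seq_len(n_trial)) {
    i <- inc[k]
    ev <- if (align == "go") 0 else tr$t_outcome[i] - tr$t_go[i]
    rng <- timeline$trial_rows[[k]]
    bt <- timeline$bin_time[rng[1]:rng[2]]
    for (m in seq_along(starts)) {
      sel <- bt >= ev + starts[m] & bt < ev + starts[m] + bin
      if (any(sel)) {
        rows <- (rng[1]:rng[2])[sel]
        out[k, , m] <- rowSums(counts[, rows, drop = FALSE])
      }
    }
  }
  attr(out, "bin_start") <- starts
  out
}

# variable-specific trial filter (indices into included trials)
.decoder_trial_filter <- function(variable, timeline, session) {
  ti <- timeline$trial_info
  contra <- if (session$hemisphere == "left") "R" else "L"
  switch(variable,
         v = which(ti$outcome == "CS+"),
         dq = which(ti$choice == contra),
         q_contra = which(ti$choice == contra),
         q_ipsi = which(ti$choice != contra),
         seq_len(nrow(ti)))
}

#' Time-resolved population decoding of a trial variable
#'
#' For each decoding time bin, draws `repeats` random neuron groups of size
#' `group_size` (without replacement within a draw) and runs
#' [nested_cv_decode()]; the per-bin performance is the mean across
#' repeats. The variable's window, alignment, and trial filter come from the
#' spec; the decoded target is the pre-update value.
#'
#' @param counts neurons x grid rows activity matrix.
#' @param timeline an [build_event_timeline()] result.
#' @param session the behavioral session.
#' @param values decision-variable data frame.
#' @param variable one of `"v"`, `"dq"`, `"q_contra"`, `"q_ipsi"`.
#' @param spec a [decoder_spec()].
#' @param group_size neurons per decoder.
#' @param repeats random neuron combinations.
#' @param seed master seed.
#' @param targets_override optional replacement target series (length =
#'   included trials, pre-filter); used by the null correction.
#' @return data frame per time bin: `time` (bin start relative to the
#'   alignment event), `r2`.
#' @export
time_resolved_decode <- function(counts, timeline, session, values, variable,
                                 spec = decoder_spec(), group_size = 20,
                                 repeats = 10, seed = 1,
                                 targets_override = NULL) {
  stopf(nrow(counts) >= group_size,
        "population has %d neurons, need >= %d", nrow(counts), group_size)
  keep <- .decoder_trial_filter(variable, timeline, session)
  stopf(length(keep) >= spec$outer_folds * 2,
        "too few trials pass the %s filter", variable)
  y_all <- if (is.null(targets_override)) {
    .U_from_values(values, timeline, variable)[, 1]
  } else targets_override
  y <- y_all[keep]
  act <- bin_activity(counts, timeline, session,
                      align = spec$align[[variable]],
                      window = spec$windows[[variable]], bin = spec$bin)
  starts <- attr(act, "bin_start")
  rows <- lapply(seq_along(starts), function(m) {
    A <- act[keep, , m]
    r2s <- vapply(seq_len(repeats), function(r) {
      idx <- withr::with_seed(child_seed(seed, m * 1000 + r),
                              sample.int(nrow(counts), group_size))
      nested_cv_decode(A[, idx, drop = FALSE], y, spec,
                       seed = child_seed(seed, m * 1000 + r))
    }, numeric(1))
    data.frame(time = starts[m], r2 = mean(r2s))
  })
  do.call(rbind, rows)
}

#' Pseudosession-corrected time-resolved decoding
#'
#' Runs the full decoding pipeline on the real target series and on `n_null`
#' surrogate series cut from a pool of other sessions' values (the same
#' surrogate draws are shared across time bins), and reports the corrected
#' performance `real - mean(null)` per time bin. Slowly drifting activity
#' can produce positive raw R2 for any slowly varying target; the
#' correction removes that nonsense-correlation component.
#'
#' @inheritParams time_resolved_decode
#' @param pool pseudosession pool matrix containing the variable's column.
#' @param n_null surrogate count (defaults to the spec's).
#' @return data frame per time bin: `time`, `r2`, `null_mean`,
#'   `corrected_r2`.
#' @export
correct_decoder_r2 <- function(counts, timeline, session, values, variable,
                               pool, spec = decoder_spec(), group_size = 20,
                               repeats = 10, seed = 1, n_null = spec$n_null) {
  real <- time_resolved_decode(counts, timeline, session, values, variable,
                               spec, group_size, repeats, seed)
  len <- nrow(timeline$trial_info)
  chunks <- draw_pseudosessions(pool[, variable, drop = FALSE], len, n_null,
                                seed = child_seed(seed, 99))
  null_mat <- vapply(seq_len(n_null), function(j) {
    time_resolved_decode(counts, timeline, session, values, variable,
                         spec, group_size, repeats,
                         seed = child_seed(seed, 200 + j),
                         targets_override = as.numeric(chunks[[j]]))$r2
  }, numeric(nrow(real)))
  null_mean <- rowMeans(as.matrix(null_mat))
  data.frame(time = real$time, r2 = real$r2, null_mean = null_mean,
             corrected_r2 = real$r2 - null_mean)
}
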