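# ---- pseudosession machinery ----------------------------------------------

#' Pool of trial-variable series for pseudosession nulls
#'
#' Pseudosessions break the alignment between neural activity and trial
#' variables while preserving each side's autocorrelation: surrogate value
#' series are contiguous chunks cut from a pool formed by concatenating the
#' trial variables of many (other) sessions.
#'
#' @param series_list list of matrices or data frames (trials x variables,
#'   shared column names).
#' @return matrix pool with the concatenated rows.
#' @export
pseudosession_pool <- function(series_list) {
  mats <- lapply(series_list, function(s) as.matrix(as.data.frame(s)))
  do.call(rbind, mats)
}

#' Draw pseudosession surrogate series from a pool
#'
#' @param pool matrix from [pseudosession_pool()].
#' @param len chunk length (the real session's trial count).
#' @param n number of surrogates.
#' @param seed RNG seed.
#' @return list of `n` matrices of `len` rows.
#' @export
draw_pseudosessions <- function(pool, len, n, seed = 1) {
  need <- len + n
  stopf(nrow(pool) >= need,
        "pseudosession pool too small: %d rows available, >= %d required",
        nrow(pool), need)
  withr::with_seed(as.integer(seed), {
    starts <- sample.int(nrow(pool) - len + 1L, n, replace = TRUE)
    lapply(starts, function(s) pool[s:(s + len - 1L), , drop = FALSE])
  })
}

# trial-variable matrix for the timeline's included trials
.U_from_values <- function(values, timeline, vars) {
  idx <- match(timeline$trial_info$trial, values$trial)
  stopf(!anyNA(idx), "values table is missing trials present in the timeline")
  as.matrix(values[idx, vars, drop = FALSE])
}

# detrend every column of a trial-variable matrix
.detrend_U <- function(U) {
  out <- apply(U, 2, detrend_trial_variable)
  colnames(out) <- colnames(U)
  out
}

# ---- null distributions ----------------------------------------------------

#' Null F-statistics for an encoding-model comparison
#'
#' Two null ensembles calibrate significance against autocorrelated data.
#' `"pseudosession"` (for trial-by-trial value gains): the gain stage is
#' refit, with kernels frozen at the real fit, for surrogate value series
#' cut from a pool of other sessions' values; the ridge penalty is re-chosen
#' for every surrogate and for both the full and the reduced (offsets-only)
#' model. `"circular_shift"` (for event kernels): the binned activity is
#' rotated by a random integer between 1/10 and 9/10 of the session length
#' and the full and history-only models are refit at the real fits'
#' penalties.
#'
#' @param fit a [fit_bilinear_encoding()] result (pseudosession mode) or the
#'   list returned by [event_significance()]'s `fits` element
#'   (circular-shift mode is normally reached through
#'   [event_significance()]).
#' @param mode `"pseudosession"` or `"circular_shift"`.
#' @param n_null ensemble size.
#' @param seed RNG seed.
#' @param pool pseudosession pool matrix (required in pseudosession mode).
#' @param vars trial-variable names receiving gains.
#' @param detrend detrend each surrogate series (as the real series was).
#' @param kernels which kernels to freeze for the gain refits (see
#'   [refit_gains()]); the default `"linear"` keeps the ensemble
#'   exchangeable with the real comparison.
#' @return data frame with one row per null: `f`, `delta_r2`.
#' @export
null_distribution <- function(fit, mode = c("pseudosession", "circular_shift"),
                              n_null = 200, seed = 1, pool = NULL,
                              vars = colnames(fit$U), detrend = TRUE,
                              kernels = c("linear", "final")) {
  mode <- match.arg(mode)
  kernels <- match.arg(kernels)
  if (mode == "pseudosession") {
    stopf(!is.null(pool), "pseudosession mode requires a value pool")
    stopf(all(vars %in% colnames(pool)),
          "pool must contain columns: %s", paste(vars, collapse = ", "))
    len <- nrow(fit$U)
    chunks <- draw_pseudosessions(pool[, vars, drop = FALSE], len, n_null, seed)
    # the offsets-only reduced model does not touch the surrogate series, so
    # its independently tuned refit is identical across nulls
    red <- refit_gains(fit, NULL, kernels = kernels)
    st0 <- if (kernels == "linear") fit$gain_stats_linear else fit$gain_stats
    rows <- lapply(chunks, function(U0) {
      U0 <- as.matrix(U0)
      if (detrend) U0 <- .detrend_U(U0)
      full <- refit_gains(fit, U0, vars, kernels = kernels)
      st <- .f_from_sse(full$sse_cv, red$sse_cv, full$dof, red$dof,
                        st0$n_rows, st0$sstot)
      data.frame(f = st$f, delta_r2 = st$delta_r2)
    })
    do.call(rbind, rows)
  } else {
    .circular_shift_nulls(fit, n_null, seed)
  }
}

#' Mean-null-corrected change in explained variance
#'
#' @param real_delta_r2 the real comparison's change in cross-validated R2.
#' @param null_delta_r2 vector of null changes.
#' @return `real_delta_r2 - mean(null_delta_r2)`.
#' @export
corrected_delta_r2 <- function(real_delta_r2, null_delta_r2) {
  stopf(length(null_delta_r2) >= 1, "need at least one null sample")
  real_delta_r2 - mean(null_delta_r2)
}

# lasso preval at fixed penalty (per-fold refits)
.lasso_preval_fixed <- function(X, y, row_fold, lambda) {
  preval <- numeric(length(y))
  for (f in sort(unique(row_fold))) {
    te <- row_fold == f
    b <- .lasso_fixed(X[!te, , drop = FALSE], y[!te], lambda)
    preval[te] <- b$beta0 +
      as.numeric(X[te, , drop = FALSE] %*% b$beta)
  }
  preval
}

.circular_shift_nulls <- function(ctx, n_null, seed) {
  n <- length(ctx$z)
  lo <- max(1L, floor(n / 10)); hi <- floor(9 * n / 10)
  withr::with_seed(as.integer(seed), {
    shifts <- lo + floor(runif(n_null) * (hi - lo + 1L))
    rows <- lapply(shifts, function(s) {
      zs <- c(tail(ctx$z, s), head(ctx$z, n - s))
      Xh <- .history_design(zs, ctx$design$timeline, ctx$config)
      Xf <- cbind(ctx$design$X, Xh)
      pf <- .lasso_preval_fixed(Xf, zs, ctx$row_fold, ctx$lambda_full)
      pr <- .lasso_preval_fixed(Xh, zs, ctx$row_fold, ctx$lambda_reduced)
      st <- f_compare(zs, pf, pr, ncol(Xf), ncol(Xh))
      data.frame(f = st$f, delta_r2 = st$delta_r2)
    })
    do.call(rbind, rows)
  })
}

#' Task-event significance of one neuron (circular-shift null)
#'
#' Compares the full linear encoding model (all event kernels + spike
#' history) to a history-only reduced model on held-out predictions, and
#' calibrates the F-statistic against circularly shifted activity. Neurons
#' passing at `alpha` are "task-modulated".
#'
#' @param z z-scored activity.
#' @param design an [build_design_matrix()] result.
#' @param n_null ensemble size.
#' @param seed RNG seed.
#' @param alpha significance threshold on the empirical p-value.
#' @param foldid optional trial-level folds.
#' @return list: `f`, `p`, `significant`, `delta_r2`, `nulls`, `fit_full`.
#' @export
event_significance <- function(z, design, n_null = 200, seed = 1,
                               alpha = 0.01, foldid = NULL) {
  config <- design$timeline$config
  full <- fit_linear_encoding(z, design, foldid = foldid, config = config,
                              seed = seed)
  Xh <- .history_design(z, design$timeline, config)
  red <- .cv_lasso(Xh, z, full$row_fold, config$lambda_grid)
  st <- f_compare(z, full$preval, red$preval, full$dof, ncol(Xh))
  ctx <- list(z = z, design = design, config = config,
              row_fold = full$row_fold,
              lambda_full = full$lambda, lambda_reduced = red$lambda)
  nulls <- .circular_shift_nulls(ctx, n_null, seed = child_seed(seed, 17))
  # at-least-as-large convention: conservative when shrinkage makes the
  # full and reduced fits (and hence all F values) coincide exactly
  p <- mean(nulls$f >= st$f)
  list(f = st$f, p = p, significant = p <= alpha, delta_r2 = st$delta_r2,
       nulls = nulls, fit_full = full)
}

# ---- per-neuron value-encoding pipeline ------------------------------------

#' Value-encoding analysis of one neuron
#'
#' The full per-neuron pipeline: z-score the binned activity over
#' kernel-covered bins, detrend the trial variables, fit the bilinear
#' kernel-and-gain model, refit the gain stage (penalty re-chosen) for the
#' full and offsets-only models, form the held-out F-statistic for the value
#' gains, and calibrate it against a pseudosession null ensemble. Reports
#' the empirical p-value, the change in cross-validated R2, and its
#' null-mean-corrected version.
#'
#' @param counts binned activity on the timeline grid (raw counts, or the
#'   continuous activity of a Gaussian-mode synthetic neuron).
#' @param design an [build_design_matrix()] result.
#' @param values decision-variable data frame (from
#'   [extract_decision_variables()]) covering the timeline's trials.
#' @param vars trial-variable columns to use as gains (e.g. `c("dq", "v")`
#'   or `c("q_contra", "q_ipsi")`).
#' @param pool pseudosession pool with the same columns.
#' @param n_null null-ensemble size.
#' @param seed RNG seed.
#' @param alpha significance threshold.
#' @param config an [encoding_config()].
#' @return list of class `neuron_encoding`: `usable`, `fit`, `f`, `p`,
#'   `significant`, `delta_r2`, `corrected_delta_r2`, `beta_gain`
#'   (full-model gain coefficients), `nulls`.
#' @export
encode_neuron <- function(counts, design, values, vars, pool,
                          n_null = 200, seed = 1, alpha = 0.01,
                          config = design$timeline$config) {
  tl <- design$timeline
  zs <- zscore_binned_spikes(counts, tl$coverage)
  if (!zs$usable) {
    return(structure(list(usable = FALSE), class = "neuron_encoding"))
  }
  U <- .detrend_U(.U_from_values(values, tl, vars))
  fit <- fit_bilinear_encoding(zs$z, design, U, config = config, seed = seed)
  # the F comparison and its nulls freeze the first-iteration kernels,
  # which are independent of the trial variables (exchangeability); the
  # reported gain coefficients come from the full bilinear fit
  full <- refit_gains(fit, U, vars, kernels = "linear")
  red <- refit_gains(fit, NULL, kernels = "linear")
  st <- .f_from_sse(full$sse_cv, red$sse_cv, full$dof, red$dof,
                    fit$gain_stats$n_rows, fit$gain_stats$sstot)
  nulls <- null_distribution(fit, "pseudosession", n_null = n_null,
                             seed = child_seed(seed, 23), pool = pool,
                             vars = vars, kernels = "linear")
  p <- mean(nulls$f >= st$f)
  structure(list(usable = TRUE, fit = fit, f = st$f, p = p,
                 significant = p <= alpha, delta_r2 = st$delta_r2,
                 corrected_delta_r2 = corrected_delta_r2(st$delta_r2,
                                                         nulls$delta_r2),
                 beta_gain = full$beta, nulls = nulls),
            class = "neuron_encoding")
}
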