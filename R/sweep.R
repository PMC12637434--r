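#' Learning/forgetting-rate sweep of value encoding
#'
#' Asks at what learning timescale a neuron's activity best reflects action
#' value: the reward-only action values (no perseveration component) are
#' recomputed for a grid of learning rates (`alpha_rew`) or forgetting rates
#' (`gamma_forget`), detrended, and the bilinear model's gain stage is refit
#' at each grid point with the kernels frozen at the behavioral-parameter
#' fit; the ridge penalty is re-chosen per grid point. Each grid point's
#' change in cross-validated R2 (full gains vs offsets-only) is corrected by
#' a pseudosession null ensemble whose surrogate series are recomputed from
#' the pool sessions at the same grid value, with the same chunk positions
#' reused across the grid.
#'
#' @param fit a [fit_bilinear_encoding()] result for the neuron (kernels are
#'   frozen from it).
#' @param session the neuron's behavioral session.
#' @param params behavioral model parameters (CS-as-reward Q-learning).
#' @param parameter `"alpha_rew"` or `"gamma_forget"`.
#' @param grid grid of rates in (0, 1] (40 linearly spaced values from 0.025
#'   to 1 by default).
#' @param pool_sessions list of sessions supplying the pseudosession pool
#'   (their reward-only values are recomputed per grid point).
#' @param n_null null-ensemble size per grid point.
#' @param seed RNG seed (chunk positions are drawn once).
#' @return data frame per grid point: `grid`, `delta_r2`, `null_mean`,
#'   `corrected_delta_r2`.
#' @export
sweep_value_timescale <- function(fit, session, params,
                                  parameter = c("alpha_rew", "gamma_forget"),
                                  grid = seq(0.025, 1, length.out = 40),
                                  pool_sessions = list(), n_null = 20,
                                  seed = 1) {
  parameter <- match.arg(parameter)
  stopf(all(grid > 0 & grid <= 1), "grid values must lie in (0, 1]")
  tl <- fit$design$timeline
  vars <- c("qrew_contra", "qrew_ipsi")
  len <- nrow(fit$U)

  qrew_at <- function(sess, rate) {
    p <- params
    p[[parameter]] <- rate
    vals <- extract_decision_variables(sess, p, "q_cs")
    vals[, c("trial", vars)]
  }
  # chunk positions shared across grid values
  pool_len <- if (length(pool_sessions) > 0) {
    sum(vapply(pool_sessions, function(s) nrow(s$trials), integer(1)))
  } else 0L
  starts <- NULL
  if (n_null > 0) {
    stopf(pool_len >= len + n_null,
          "pseudosession pool too small: %d rows available, >= %d required",
          pool_len, len + n_null)
    starts <- withr::with_seed(as.integer(seed),
                               sample.int(pool_len - len + 1L, n_null,
                                          replace = TRUE))
  }

  # the offsets-only reduced model does not involve the trial variables, so
  # its (independently penalty-tuned) refit is shared across grid points
  red <- refit_gains(fit, NULL)
  st0 <- fit$gain_stats
  rows <- lapply(grid, function(g) {
    vals <- qrew_at(session, g)
    U <- .detrend_U(.U_from_values(vals, tl, vars))
    full <- refit_gains(fit, U, vars)
    dr2 <- .f_from_sse(full$sse_cv, red$sse_cv, full$dof, red$dof,
                       st0$n_rows, st0$sstot)$delta_r2
    null_mean <- NA_real_
    if (n_null > 0) {
      pool <- do.call(rbind, lapply(pool_sessions, function(s)
        as.matrix(qrew_at(s, g)[, vars, drop = FALSE])))
      drs <- vapply(starts, function(s0) {
        U0 <- .detrend_U(pool[s0:(s0 + len - 1L), , drop = FALSE])
        fl <- refit_gains(fit, U0, vars)
        .f_from_sse(fl$sse_cv, red$sse_cv, fl$dof, red$dof,
                    st0$n_rows, st0$sstot)$delta_r2
      }, numeric(1))
      null_mean <- mean(drs)
    }
    data.frame(grid = g, delta_r2 = dr2, null_mean = null_mean,
               corrected_delta_r2 = if (is.na(null_mean)) dr2
                                    else dr2 - null_mean)
  })
  do.call(rbind, rows)
}
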