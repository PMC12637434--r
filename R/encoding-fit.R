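# ---- penalized-regression building blocks --------------------------------

# Lasso with cross-validated penalty over the configured log grid; returns
# the chosen penalty, coefficients, and prevalidated (held-out) predictions.
.cv_lasso <- function(X, y, row_fold, lambda) {
  lam <- sort(lambda, decreasing = TRUE)
  cv <- glmnet::cv.glmnet(X, y, lambda = lam, foldid = row_fold, alpha = 1,
                          standardize = FALSE, keep = TRUE, thresh = 1e-5)
  idx <- which.min(cv$cvm)
  beta <- as.numeric(coef(cv$glmnet.fit, s = cv$lambda[idx]))
  list(lambda = cv$lambda[idx], beta0 = beta[1], beta = beta[-1],
       preval = as.numeric(cv$fit.preval[, idx]))
}

# Lasso refit at a fixed penalty (short warm-start path ending at lambda).
.lasso_fixed <- function(X, y, lambda) {
  path <- lambda * c(25, 5, 1)
  fit <- glmnet::glmnet(X, y, lambda = path, alpha = 1, standardize = FALSE,
                        thresh = 1e-7)
  beta <- as.numeric(coef(fit, s = lambda, exact = FALSE))
  list(lambda = lambda, beta0 = beta[1], beta = beta[-1])
}

# Exact ridge solutions (objective RSS + lambda * ||beta||^2, no intercept)
# for a whole penalty grid at once via one SVD.
.ridge_solve <- function(X, y, lambda_vec) {
  s <- svd(X)
  uty <- crossprod(s$u, y)
  shrink <- outer(s$d, lambda_vec, function(d, l) d / (d^2 + l))
  s$v %*% (shrink * as.numeric(uty))
}

# Ridge with 5-fold cross-validated penalty; `offset` is subtracted from the
# response before fitting and added back to predictions.
.cv_ridge <- function(X, y, row_fold, lambda, offset = 0) {
  yo <- y - offset
  preval <- matrix(NA_real_, length(y), length(lambda))
  for (f in sort(unique(row_fold))) {
    te <- row_fold == f
    beta <- .ridge_solve(X[!te, , drop = FALSE], yo[!te], lambda)
    preval[te, ] <- as.matrix(X[te, , drop = FALSE] %*% beta)
  }
  cvm <- colMeans((yo - preval)^2)
  idx <- which.min(cvm)
  beta <- .ridge_solve(X, yo, lambda[idx])[, 1]
  list(lambda = lambda[idx], beta = beta,
       preval = preval[, idx] + offset,
       fitted = as.numeric(X %*% beta) + offset)
}

# Ridge at a fixed penalty with prevalidated predictions from the same folds.
.ridge_fixed <- function(X, y, row_fold, lambda, offset = 0) {
  yo <- y - offset
  preval <- numeric(length(y))
  for (f in sort(unique(row_fold))) {
    te <- row_fold == f
    beta <- .ridge_solve(X[!te, , drop = FALSE], yo[!te], lambda)
    preval[te] <- as.numeric(X[te, , drop = FALSE] %*% beta)
  }
  beta <- .ridge_solve(X, yo, lambda)[, 1]
  list(lambda = lambda, beta = beta, preval = preval + offset,
       fitted = as.numeric(X %*% beta) + offset)
}

.r2 <- function(y, pred) 1 - sum((y - pred)^2) / sum((y - mean(y))^2)

# ---- gain-stage sufficient statistics -------------------------------------
# The gain design has one column per event (the kernel prediction z_i) and
# one per event x trial variable (z_i scaled by a per-trial constant), so
# every Gram/cross-product needed for ridge fitting and held-out SSEs
# collapses into per-trial statistics of Z. Null ensembles and sweeps refit
# gains thousands of times; working in this collapsed space makes each
# refit O(trials x 18^2) instead of O(grid rows).

.gain_stats <- function(Z, y, offset, row_trial) {
  K <- ncol(Z)
  ye <- y - offset
  n_trials <- max(row_trial)
  H <- t(rowsum(Z * ye, row_trial))               # K x trials
  q <- as.numeric(rowsum(ye^2, row_trial))
  pairs <- which(upper.tri(diag(K), diag = TRUE), arr.ind = TRUE)
  P <- Z[, pairs[, 1], drop = FALSE] * Z[, pairs[, 2], drop = FALSE]
  Gp <- t(rowsum(P, row_trial))                   # n_pairs x trials
  list(K = K, H = H, q = q, Gp = Gp, pairs = pairs, n_trials = n_trials,
       sstot = sum((y - mean(y))^2), n_rows = length(y),
       events = colnames(Z))
}

# expand per-trial Z-gram pieces into the full gain-design Gram and
# cross-products for an augmented-variable matrix Ua (trials x (1 + K_vars))
.gain_xtx <- function(stats, Ua, trials) {
  K <- stats$K; A <- ncol(Ua)
  p <- K * A
  XtX <- matrix(0, p, p)
  # per-pair sums weighted by u_a * u_b over the selected trials
  for (a in seq_len(A)) for (b in a:A) {
    w <- Ua[trials, a] * Ua[trials, b]
    g <- as.numeric(stats$Gp[, trials, drop = FALSE] %*% w)
    Gm <- matrix(0, K, K)
    Gm[cbind(stats$pairs[, 1], stats$pairs[, 2])] <- g
    Gm[cbind(stats$pairs[, 2], stats$pairs[, 1])] <- g
    ia <- seq(a, p, by = A); ib <- seq(b, p, by = A)
    XtX[ia, ib] <- Gm
    XtX[ib, ia] <- t(Gm)
  }
  Xty <- numeric(p)
  for (a in seq_len(A)) {
    Xty[seq(a, p, by = A)] <-
      as.numeric(stats$H[, trials, drop = FALSE] %*% Ua[trials, a])
  }
  list(XtX = XtX, Xty = Xty, q = sum(stats$q[trials]))
}

# Ridge gain fit with 5-fold CV penalty selection (or a fixed penalty),
# entirely in sufficient-statistic space. Returns pooled held-out SSE at
# the chosen penalty, matching a row-space prevalidated fit exactly.
.gain_fit_ss <- function(stats, U, vars, trial_fold, lambda_grid,
                         lambda = NULL) {
  n_tr <- stats$n_trials
  Ua <- if (is.null(U) || length(vars) == 0) {
    matrix(1, n_tr, 1)
  } else {
    cbind(1, as.matrix(U[, vars, drop = FALSE]))
  }
  A <- ncol(Ua); K <- stats$K; p <- K * A
  folds <- sort(unique(trial_fold))
  parts <- lapply(folds, function(f) .gain_xtx(stats, Ua, which(trial_fold == f)))
  tot <- list(XtX = Reduce(`+`, lapply(parts, `[[`, "XtX")),
              Xty = Reduce(`+`, lapply(parts, function(x) x$Xty)),
              q = sum(vapply(parts, `[[`, numeric(1), "q")))
  lam <- if (is.null(lambda)) sort(lambda_grid) else lambda
  sse <- numeric(length(lam))
  for (i in seq_along(folds)) {
    XtX_tr <- tot$XtX - parts[[i]]$XtX
    Xty_tr <- tot$Xty - parts[[i]]$Xty
    eg <- eigen(XtX_tr, symmetric = TRUE)
    qty <- crossprod(eg$vectors, Xty_tr)
    B <- eg$vectors %*% (qty[, 1] / outer(eg$values, lam, `+`))
    XtXB <- parts[[i]]$XtX %*% B
    sse <- sse + parts[[i]]$q - 2 * colSums(B * parts[[i]]$Xty) +
      colSums(B * XtXB)
  }
  idx <- which.min(sse)
  lambda_star <- lam[idx]
  eg <- eigen(tot$XtX, symmetric = TRUE)
  qty <- crossprod(eg$vectors, tot$Xty)
  beta <- as.numeric(eg$vectors %*% (qty[, 1] / (eg$values + lambda_star)))
  nm <- as.vector(t(outer(stats$events,
                          c("offset", if (A > 1) vars else NULL),
                          paste, sep = ":")))
  names(beta) <- nm
  list(beta = beta, lambda = lambda_star, sse_cv = sse[idx],
       r2_cv = 1 - sse[idx] / stats$sstot, dof = p, Ua = Ua)
}

# ---- linear (kernel-only) encoding model ----------------------------------

#' Fit the linear encoding model of one neuron
#'
#' Regresses z-scored 10 ms binned activity on the event design matrix plus
#' spike-history predictors with lasso regularization; the penalty is chosen
#' by cross-validation over the configured log grid (minimum mean CV error)
#' with folds stratified over trials by block side, choice, and outcome.
#'
#' @param z z-scored activity vector on the timeline grid (see
#'   [zscore_binned_spikes()]).
#' @param design an [build_design_matrix()] result.
#' @param foldid optional trial-level fold assignment; defaults to
#'   [stratified_trial_folds()].
#' @param config an [encoding_config()].
#' @param seed seed for the fold assignment.
#' @return list of class `kernel_fit`: `beta0`, `beta_event` (named list of
#'   basis coefficients per event), `beta_hist`, `kernels` (per event:
#'   `time`, `value` on the bin grid), `lambda`, `preval` (held-out
#'   predictions), `r2_cv`, `dof` (number of predictors), `foldid`,
#'   `row_fold`.
#' @export
fit_linear_encoding <- function(z, design, foldid = NULL,
                                config = design$timeline$config, seed = 1) {
  tl <- design$timeline
  if (is.null(foldid))
    foldid <- stratified_trial_folds(tl$trial_info, config$n_folds, seed)
  row_fold <- foldid[tl$row_trial]
  Xh <- .history_design(z, tl, config)
  X <- cbind(design$X, Xh)
  fit <- .cv_lasso(X, z, row_fold, config$lambda_grid)
  n_ev <- ncol(design$X)
  beta_event <- lapply(design$blocks, function(cols) fit$beta[cols])
  beta_hist <- fit$beta[n_ev + seq_len(ncol(Xh))]
  kernels <- lapply(.event_names, function(e) {
    B <- design$bases[[e]]
    data.frame(time = B$times,
               value = as.numeric(B$matrix %*% beta_event[[e]]))
  })
  names(kernels) <- .event_names
  structure(list(beta0 = fit$beta0, beta_event = beta_event,
                 beta_hist = beta_hist, kernels = kernels,
                 lambda = fit$lambda, preval = fit$preval,
                 r2_cv = .r2(z, fit$preval), dof = ncol(X),
                 foldid = foldid, row_fold = row_fold),
            class = "kernel_fit")
}

# ---- bilinear (kernel x gain) encoding model ------------------------------

# Gain-stage design: one offset column per event (the kernel prediction
# z_i) and one column per event x trial variable (z_i scaled by U_k of the
# row's trial).
.gain_design <- function(Z, U, row_trial, vars = colnames(U)) {
  cols <- list()
  nm <- character(0)
  for (i in seq_len(ncol(Z))) {
    e <- colnames(Z)[i]
    cols[[length(cols) + 1L]] <- Z[, i]
    nm <- c(nm, paste0(e, ":offset"))
    for (k in vars) {
      cols[[length(cols) + 1L]] <- Z[, i] * U[row_trial, k]
      nm <- c(nm, paste0(e, ":", k))
    }
  }
  Xg <- do.call(cbind, cols)
  colnames(Xg) <- nm
  Xg
}

#' Fit the bilinear encoding model of one neuron
#'
#' Extends the linear model with trial-by-trial multiplicative gains:
#' each event kernel is scaled on trial T by
#' `G_i(T) = b_i0 + sum_k b_ik U_k(T)` where `U_k` are trial variables such
#' as relative value and state value. Fitting alternates between (a) the
#' kernels and intercept given fixed gains (lasso, kernels unit-normalized
#' after each pass) and (b) the gains given fixed kernels (ridge, with the
#' intercept and spike-history prediction supplied as a fixed offset). Both
#' penalties are chosen by cross-validation on the first iteration and then
#' frozen. Gains start at 1; the first iteration therefore coincides with
#' [fit_linear_encoding()]. Iteration stops once every coefficient has
#' changed by at most `config$tol` for three consecutive iterations, or at
#' `config$max_iter`.
#'
#' @inheritParams fit_linear_encoding
#' @param U matrix of trial variables (included trials x variables, with
#'   column names), detrended upstream.
#' @return list of class `bilinear_fit` with the kernel-stage results
#'   (`beta0`, `beta_event`, `beta_hist`, `kernels`, `lambda_lasso`), the
#'   gain stage (`beta_gain`, `gains` (trial x event matrix),
#'   `lambda_ridge`), `Z` (per-row kernel predictions), `offset_vec`,
#'   `n_iter`, `converged`, `z`, `U`, `row_trial`, `row_fold`, `foldid`,
#'   `design`, `config`.
#' @export
fit_bilinear_encoding <- function(z, design, U, foldid = NULL,
                                  config = design$timeline$config, seed = 1) {
  tl <- design$timeline
  stopf(is.matrix(U) && nrow(U) == max(tl$row_trial),
        "U must be an included-trials x variables matrix")
  if (is.null(colnames(U))) colnames(U) <- paste0("u", seq_len(ncol(U)))
  if (is.null(foldid))
    foldid <- stratified_trial_folds(tl$trial_info, config$n_folds, seed)
  row_fold <- foldid[tl$row_trial]
  rt <- tl$row_trial
  Xh <- .history_design(z, tl, config)
  n_ev_types <- length(.event_names)
  G <- matrix(1, max(rt), n_ev_types)

  lambda_lasso <- NULL; lambda_ridge <- NULL
  prev_coef <- NULL; stable <- 0L; it <- 0L
  beta_event <- NULL; beta_hist <- NULL; beta0 <- NULL
  beta_gain <- NULL; Z <- NULL; offset_vec <- NULL
  gain_stats <- NULL; gain_stats_linear <- NULL
  repeat {
    it <- it + 1L
    Xs <- do.call(cbind, c(
      lapply(seq_along(design$blocks), function(i)
        Matrix::Diagonal(x = G[rt, i]) %*% design$X[, design$blocks[[i]],
                                                    drop = FALSE]),
      list(Xh)))
    if (is.null(lambda_lasso)) {
      kf <- .cv_lasso(Xs, z, row_fold, config$lambda_grid)
      lambda_lasso <- kf$lambda
    } else {
      kf <- .lasso_fixed(Xs, z, lambda_lasso)
    }
    n_ev <- ncol(design$X)
    beta0 <- kf$beta0
    beta_event <- lapply(design$blocks, function(cols) kf$beta[cols])
    beta_hist <- kf$beta[n_ev + seq_len(ncol(Xh))]
    # unit-normalize each kernel; zero kernels stay zero
    for (e in .event_names) {
      kv <- design$bases[[e]]$matrix %*% beta_event[[e]]
      nrm <- sqrt(sum(kv^2))
      if (nrm > 0) beta_event[[e]] <- beta_event[[e]] / nrm
    }
    Z <- vapply(.event_names, function(e)
      as.numeric(design$X[, design$blocks[[e]], drop = FALSE] %*%
                   beta_event[[e]]),
      numeric(tl$n_rows))
    colnames(Z) <- .event_names
    offset_vec <- beta0 + as.numeric(Xh %*% beta_hist)

    gain_stats <- .gain_stats(Z, z, offset_vec, rt)
    if (it == 1L) gain_stats_linear <- gain_stats
    gf <- .gain_fit_ss(gain_stats, U, colnames(U), foldid,
                       config$lambda_grid, lambda = lambda_ridge)
    if (is.null(lambda_ridge)) lambda_ridge <- gf$lambda
    beta_gain <- gf$beta
    K <- ncol(U)
    for (i in seq_len(n_ev_types)) {
      base_i <- (i - 1L) * (K + 1L)
      G[, i] <- beta_gain[base_i + 1L] +
        as.matrix(U) %*% beta_gain[base_i + 1L + seq_len(K)]
    }
    coefs <- c(beta0, unlist(beta_event), beta_hist, beta_gain)
    if (!is.null(prev_coef)) {
      if (max(abs(coefs - prev_coef)) <= config$tol) stable <- stable + 1L
      else stable <- 0L
    }
    prev_coef <- coefs
    if (stable >= 3L || it >= config$max_iter) break
  }
  kernels <- lapply(.event_names, function(e) {
    B <- design$bases[[e]]
    data.frame(time = B$times,
               value = as.numeric(B$matrix %*% beta_event[[e]]))
  })
  names(kernels) <- .event_names
  structure(list(beta0 = beta0, beta_event = beta_event,
                 beta_hist = beta_hist, kernels = kernels,
                 beta_gain = beta_gain, gains = G, Z = Z,
                 offset_vec = offset_vec, gain_stats = gain_stats,
                 gain_stats_linear = gain_stats_linear,
                 lambda_lasso = lambda_lasso, lambda_ridge = lambda_ridge,
                 n_iter = it, converged = stable >= 3L,
                 z = z, U = U, row_trial = rt, row_fold = row_fold,
                 foldid = foldid, design = design, config = config),
            class = "bilinear_fit")
}

#' Refit the value gains with kernels held fixed
#'
#' Used for model comparison, null ensembles, and the learning-rate sweep:
#' the final kernels (and intercept + spike-history offset) from a bilinear
#' fit are frozen and only the gain stage is re-estimated by ridge for a
#' given set of trial variables. The ridge penalty is re-chosen by
#' cross-validation unless `lambda` is supplied.
#'
#' @param fit a [fit_bilinear_encoding()] result.
#' @param U trial-variable matrix (included trials x variables); `NULL`
#'   fits the offsets-only (no trial variable) model.
#' @param vars which columns of `U` get gain terms (default all).
#' @param lambda optional fixed ridge penalty.
#' @param kernels `"final"` uses the kernels from the last bilinear
#'   iteration (best gain estimates); `"linear"` uses the first-iteration
#'   (gains-equal-1) kernels, which never saw the trial variables and so
#'   keep real-vs-pseudosession comparisons exchangeable. Significance
#'   testing uses `"linear"`.
#' @return list: `beta`, `lambda`, `sse_cv` (pooled held-out SSE), `r2_cv`,
#'   `dof`.
#' @export
refit_gains <- function(fit, U = fit$U, vars = colnames(U), lambda = NULL,
                        kernels = c("final", "linear")) {
  kernels <- match.arg(kernels)
  stats <- if (kernels == "linear") fit$gain_stats_linear else fit$gain_stats
  if (is.null(U)) vars <- character(0)
  .gain_fit_ss(stats, U, vars, fit$foldid, fit$config$lambda_grid,
               lambda = lambda)
}

# F-statistic and delta-R2 from pooled held-out SSEs (same definition as
# f_compare, with the predictions already reduced to their SSEs)
.f_from_sse <- function(sse_full, sse_reduced, dof_full, dof_reduced,
                        n, sstot) {
  stopf(dof_full > dof_reduced,
        "full model must have more predictors than the reduced model")
  ddof <- dof_full - dof_reduced
  list(f = ((sse_reduced - sse_full) / ddof) / (sse_full / n),
       delta_r2 = (sse_reduced - sse_full) / sstot,
       sse_full = sse_full, sse_reduced = sse_reduced, delta_dof = ddof)
}

#' F-statistic comparing nested encoding models on held-out predictions
#'
#' `F = (dSSE / dDOF) / MSE_full`, where both sums of squared errors come
#' from pooled five-fold cross-validated predictions, `dDOF` is the
#' difference in predictor counts, and `MSE_full = SSE_full / n`. Because
#' the SSEs are held-out, F can be negative and is reported as-is; empirical
#' significance comes from comparing against a null ensemble, not an F
#' distribution.
#'
#' @param y observed response.
#' @param pred_full,pred_reduced held-out predictions of the two models.
#' @param dof_full,dof_reduced predictor counts (full > reduced).
#' @return list of class `encoding_stats`: `sse_full`, `sse_reduced`,
#'   `delta_dof`, `mse_full`, `f`, `r2_full`, `r2_reduced`, `delta_r2`.
#' @export
f_compare <- function(y, pred_full, pred_reduced, dof_full, dof_reduced) {
  stopf(dof_full > dof_reduced,
        "full model must have more predictors than the reduced model")
  sse_f <- sum((y - pred_full)^2)
  sse_r <- sum((y - pred_reduced)^2)
  ddof <- dof_full - dof_reduced
  mse_f <- sse_f / length(y)
  structure(list(sse_full = sse_f, sse_reduced = sse_r, delta_dof = ddof,
                 mse_full = mse_f, f = ((sse_r - sse_f) / ddof) / mse_f,
                 r2_full = .r2(y, pred_full), r2_reduced = .r2(y, pred_reduced),
                 delta_r2 = .r2(y, pred_full) - .r2(y, pred_reduced)),
            class = "encoding_stats")
}
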