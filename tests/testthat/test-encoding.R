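test_that("raised-cosine bases tile their windows with the stated resolution", {
  b1 <- make_basis("linear_cosine", c(0, 1))
  expect_identical(b1$n_dof, 40L)
  b2 <- make_basis("linear_cosine", c(0, 2))
  expect_identical(b2$n_dof, 80L)
  # partition of unity (constant sum) in the window interior
  s <- rowSums(b1$matrix)
  interior <- b1$times > 0.05 & b1$times < 0.95
  expect_lt(diff(range(s[interior])), 1e-6)
  # movement window spans negative lags
  bm <- make_basis("linear_cosine", c(-0.5, 0.5))
  expect_identical(bm$n_dof, 40L)
  expect_lt(min(bm$times), 0)
  # history basis is strictly causal with log-spaced support
  bh <- make_basis("log_cosine_history")
  expect_identical(bh$n_dof, 10L)
  expect_gte(min(bh$times), 0.01)
  expect_error(make_basis("linear_cosine", c(0.5, 0.5)), "positive")
})

test_that("z-scoring uses only kernel-covered bins and flags dead neurons", {
  fx <- make_encoding_fixture(30, seed = 11)
  counts <- withr::with_seed(1, rpois(fx$timeline$n_rows, 2))
  zs <- zscore_binned_spikes(counts, fx$timeline$coverage)
  expect_true(zs$usable)
  expect_lt(abs(mean(zs$z[fx$timeline$coverage])), 1e-10)
  expect_lt(abs(sd(zs$z[fx$timeline$coverage]) - 1), 1e-10)
  # two-pass oracle
  mu <- mean(counts[fx$timeline$coverage])
  sg <- sd(counts[fx$timeline$coverage])
  expect_equal(zs$z, (counts - mu) / sg, tolerance = 1e-12)
  flat <- zscore_binned_spikes(rep(3, fx$timeline$n_rows),
                               fx$timeline$coverage)
  expect_false(flat$usable)
})

test_that("each analyzable trial carries exactly one go cue and one outcome event", {
  fx <- make_encoding_fixture(40, seed = 12)
  ev <- fx$timeline$events
  n_inc <- sum(fx$timeline$included)
  expect_identical(sum(ev$event == "go"), n_inc)
  expect_identical(sum(ev$event %in% c("cs_plus", "cs_minus")), n_inc)
  expect_identical(sum(ev$event %in% c("move_l", "move_r")), n_inc)
  # indicator totals agree with the trial table
  tr <- fx$session$trials[fx$timeline$included, ]
  expect_identical(sum(ev$event == "cs_plus"), sum(tr$r == 1))
  expect_identical(sum(ev$event == "stim"), sum(tr$stim_collected))
  # a session without rewards has no CS+ or stimulation indicators
  s0 <- simulate_session(task_config(p_high = 0.9999, p_low = 0.9998),
                         agent_random(), 12, seed = 1)
  s0$trials$r <- 0L
  s0$trials$outcome <- "CS-"
  s0$trials$stim_collected <- FALSE
  s0$trials$t_stim <- NA_real_
  tl0 <- build_event_timeline(s0, small_encoding_config())
  expect_identical(sum(tl0$events$event %in% c("cs_plus", "stim")), 0L)
  d0 <- build_design_matrix(tl0)
  expect_equal(sum(abs(d0$X[, d0$blocks$cs_plus])), 0)
})

test_that("the design matrix equals a brute-force convolution oracle", {
  fx <- make_encoding_fixture(5, seed = 13)
  tl <- fx$timeline; cfg <- fx$config
  X <- as.matrix(fx$design$X)
  oracle <- matrix(0, tl$n_rows, ncol(X))
  for (e in event_names) {
    B <- fx$design$bases[[e]]
    cols <- fx$design$blocks[[e]]
    occ <- tl$events[tl$events$event == e, , drop = FALSE]
    for (r in seq_len(nrow(occ))) {
      rng <- tl$trial_rows[[occ$row[r]]]
      for (gi in rng[1]:rng[2]) {
        lag <- gi - occ$bin[r]           # bins since the event
        tt <- cfg$spans[[e]][1] + (lag - round(cfg$spans[[e]][1] / cfg$bin) + 0.5) * cfg$bin
        # evaluate each basis function at this lag if inside the window
        li <- lag - round(cfg$spans[[e]][1] / cfg$bin) + 1L
        if (li >= 1 && li <= nrow(B$matrix)) {
          oracle[gi, cols] <- oracle[gi, cols] + B$matrix[li, ]
        }
      }
    }
  }
  expect_equal(X, oracle, tolerance = 1e-12, ignore_attr = TRUE)
  # single delta: a lone basis column translated to the event bin
  ev1 <- tl$events[tl$events$event == "go", ][1, ]
  B <- fx$design$bases$go
  col1 <- X[, fx$design$blocks$go[1]]
  seg <- col1[ev1$bin:(ev1$bin + nrow(B$matrix) - 1L)]
  expect_equal(seg, B$matrix[, 1], tolerance = 1e-12, ignore_attr = TRUE)
})

test_that("noiseless in-span neurons are recovered nearly perfectly by the linear fit", {
  fx <- make_encoding_fixture(60, seed = 14)
  nr <- ground_truth_neuron(fx$design,
                            gain_offset = setNames(rep(2, 6), event_names),
                            noise_sd = 0, seed = 21)
  g <- generate_neuron_spikes(nr, fx$design, NULL, seed = 22)
  # direct convolution oracle for the signal itself
  manual <- rep(0, fx$timeline$n_rows)
  for (i in seq_along(event_names)) {
    e <- event_names[i]
    manual <- manual + 2 *
      as.numeric(fx$design$X[, fx$design$blocks[[e]]] %*% nr$kernel_coef[[e]])
  }
  expect_equal(g$counts, manual, tolerance = 1e-12)

  zs <- zscore_binned_spikes(g$counts, fx$timeline$coverage)
  lf <- fit_linear_encoding(zs$z, fx$design, seed = 1)
  expect_gt(lf$r2_cv, 0.99)
  # fitted kernels match the planted shapes up to the norm/gain
  # factorization (windows overlap in time, so per-kernel attribution is
  # slightly softer than the near-perfect overall fit)
  for (e in c("go", "cs_plus", "cs_minus")) {
    truth <- as.numeric(fx$design$bases[[e]]$matrix %*% nr$kernel_coef[[e]])
    fitk <- lf$kernels[[e]]$value
    expect_gt(abs(cor(truth, fitk)), 0.95)
  }
})

test_that("pure-noise neurons score near zero held-out R2 and heavy penalties zero the kernels", {
  fx <- make_encoding_fixture(60, seed = 15)
  z <- withr::with_seed(31, rnorm(fx$timeline$n_rows))
  lf <- fit_linear_encoding(z, fx$design, seed = 1)
  expect_lt(abs(lf$r2_cv), 0.02)
  # lasso shrinkage limit
  Xh <- valuecode:::.history_design(z, fx$timeline, fx$config)
  bf <- valuecode:::.lasso_fixed(cbind(fx$design$X, Xh), z, 1e5)
  expect_equal(sum(abs(bf$beta)), 0)
})

test_that("the F-statistic reproduces hand arithmetic and rejects non-nested input", {
  y <- rep(0, 10)
  pred_full <- rep(sqrt(0.8), 10)     # SSE 8
  pred_red <- rep(sqrt(1.2), 10)      # SSE 12
  st <- f_compare(y, pred_full, pred_red, dof_full = 5, dof_reduced = 3)
  expect_equal(st$f, 2.5)
  expect_equal(st$sse_full, 8)
  expect_equal(st$delta_dof, 2)
  expect_equal(f_compare(y, pred_full, pred_full, 5, 3)$f, 0)
  expect_error(f_compare(y, pred_full, pred_red, 3, 3), "more predictors")
  # ratio homogeneity: scaling both residual sets leaves F unchanged
  st2 <- f_compare(2 * y, 2 * pred_full, 2 * pred_red, 5, 3)
  expect_equal(st2$f, st$f)
})

test_that("sufficient-statistic gain ridge equals the row-space ridge exactly", {
  withr::with_seed(41, {
    n_tr <- 40; rows_per <- 12
    rt <- rep(seq_len(n_tr), each = rows_per)
    Z <- matrix(rnorm(n_tr * rows_per * 3), ncol = 3)
    colnames(Z) <- c("a", "b", "c")
    U <- matrix(rnorm(n_tr * 2), ncol = 2); colnames(U) <- c("dq", "v")
    y <- rnorm(length(rt)); off <- rnorm(length(rt), 0, 0.1)
    foldid <- rep(1:5, length.out = n_tr)
  })
  lam <- 10^seq(-3, 3, length.out = 21)
  st <- valuecode:::.gain_stats(Z, y, off, rt)
  gs <- valuecode:::.gain_fit_ss(st, U, c("dq", "v"), foldid, lam)
  Xg <- valuecode:::.gain_design(Z, U, rt)
  rs <- valuecode:::.cv_ridge(Xg, y, foldid[rt], lam, off)
  expect_equal(gs$lambda, rs$lambda)
  expect_equal(unname(gs$beta[colnames(Xg)]), unname(rs$beta),
               tolerance = 1e-10)
  expect_equal(gs$sse_cv, sum((y - rs$preval)^2), tolerance = 1e-8)
})

test_that("the bilinear model recovers planted gains and collapses to the linear fit", {
  fx <- make_encoding_fixture(80, seed = 16)
  U_raw <- as.matrix(fx$values[fx$timeline$included, c("dq", "v")])
  colnames(U_raw) <- c("dq", "v")
  U <- apply(U_raw, 2, detrend_trial_variable); colnames(U) <- c("dq", "v")
  gc <- matrix(0, 6, 2, dimnames = list(event_names, c("dq", "v")))
  gc["go", "dq"] <- 0.6
  nr <- ground_truth_neuron(fx$design,
                            gain_offset = setNames(rep(2, 6), event_names),
                            gain_coef = gc, noise_sd = 0.5, seed = 51)
  g <- generate_neuron_spikes(nr, fx$design, U, seed = 52)
  zs <- zscore_binned_spikes(g$counts, fx$timeline$coverage)
  fit <- fit_bilinear_encoding(zs$z, fx$design, U, seed = 1)
  expect_true(fit$converged)
  # the planted go-cue gain is recovered with the right sign and dominates
  gains_dq <- fit$beta_gain[paste0(event_names, ":dq")]
  expect_gt(fit$beta_gain[["go:dq"]], 0)
  expect_identical(names(which.max(abs(gains_dq))), "go:dq")
  # kernels carry unit norm after the final iteration
  for (e in event_names) {
    nrm <- sqrt(sum(fit$kernels[[e]]$value^2))
    expect_true(nrm < 1e-8 || abs(nrm - 1) < 1e-8)
  }
  # adding the gains improves held-out fit for this neuron
  full <- refit_gains(fit)
  red <- refit_gains(fit, NULL)
  expect_gt(full$r2_cv, red$r2_cv)

  # a single iteration with gains frozen at 1 is exactly the linear model
  cfg1 <- fx$config; cfg1$max_iter <- 1
  fit1 <- fit_bilinear_encoding(zs$z, fx$design, U, config = cfg1,
                                foldid = fit$foldid)
  lf <- fit_linear_encoding(zs$z, fx$design, foldid = fit$foldid,
                            config = fx$config)
  expect_equal(fit1$lambda_lasso, lf$lambda)
  for (e in event_names) {
    kb <- lf$beta_event[[e]]
    nrm <- sqrt(sum((fx$design$bases[[e]]$matrix %*% kb)^2))
    if (nrm > 0) kb <- kb / nrm
    expect_equal(fit1$beta_event[[e]], kb, tolerance = 1e-10)
  }
})

test_that("value-blind neurons yield near-zero gain effects", {
  fx <- make_encoding_fixture(80, seed = 17)
  U_raw <- as.matrix(fx$values[fx$timeline$included, c("dq", "v")])
  colnames(U_raw) <- c("dq", "v")
  U <- apply(U_raw, 2, detrend_trial_variable); colnames(U) <- c("dq", "v")
  nr <- ground_truth_neuron(fx$design,
                            gain_offset = setNames(rep(2, 6), event_names),
                            noise_sd = 1, seed = 61)
  g <- generate_neuron_spikes(nr, fx$design, NULL, seed = 62)
  zs <- zscore_binned_spikes(g$counts, fx$timeline$coverage)
  fit <- fit_bilinear_encoding(zs$z, fx$design, U, seed = 1)
  full <- refit_gains(fit)
  red <- refit_gains(fit, NULL)
  st <- valuecode:::.f_from_sse(full$sse_cv, red$sse_cv, full$dof, red$dof,
                                fit$gain_stats$n_rows, fit$gain_stats$sstot)
  expect_lt(abs(st$delta_r2), 0.01)
  # the value terms buy essentially no held-out variance
  expect_lt(full$r2_cv - red$r2_cv, 0.01)
})
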