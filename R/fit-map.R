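# ---- model registry -------------------------------------------------------

# Parameter layout per model: names, which are rates (fit on the log-odds
# scale), and how to build the parameter object from a named natural vector.
.model_info <- function(model) {
  switch(model,
    q_cs = ,
    q_rpe = list(
      names = c("alpha_rew", "alpha_stay", "gamma_forget",
                "beta_rew", "beta_stay", "bias"),
      rates = c(TRUE, TRUE, TRUE, FALSE, FALSE, FALSE),
      prior_sd = c(1, 1, 1, 5, 5, 5),
      build = function(p, model) {
        rl_params_q(p[["alpha_rew"]], p[["alpha_stay"]], p[["gamma_forget"]],
                    p[["beta_rew"]], p[["beta_stay"]], p[["bias"]],
                    reward_semantics = if (model == "q_rpe") "stim_as_rpe"
                                       else "cs_as_reward")
      }),
    kappa = list(
      names = c("alpha_rew", "alpha_stay", "gamma_forget",
                "beta_rew", "beta_stay", "bias", "kappa"),
      rates = c(TRUE, TRUE, TRUE, FALSE, FALSE, FALSE, FALSE),
      prior_sd = c(1, 1, 1, 5, 5, 5, 1),
      build = function(p, model) {
        kappa_params(rl_params_q(p[["alpha_rew"]], p[["alpha_stay"]],
                                 p[["gamma_forget"]], p[["beta_rew"]],
                                 p[["beta_stay"]], p[["bias"]]),
                     kappa = p[["kappa"]])
      }),
    reinforce = list(
      names = c("alpha_win", "alpha_loss", "beta_win", "beta_loss", "bias"),
      rates = c(TRUE, TRUE, FALSE, FALSE, FALSE),
      prior_sd = c(1, 1, 5, 5, 5),
      build = function(p, model) {
        rl_params_policy(p[["alpha_win"]], p[["alpha_loss"]], p[["beta_win"]],
                         p[["beta_loss"]], p[["bias"]], family = "reinforce")
      }),
    actor_critic = list(
      names = c("alpha_win", "alpha_loss", "alpha_critic",
                "beta_win", "beta_loss", "bias"),
      rates = c(TRUE, TRUE, TRUE, FALSE, FALSE, FALSE),
      prior_sd = c(1, 1, 1, 5, 5, 5),
      build = function(p, model) {
        rl_params_policy(p[["alpha_win"]], p[["alpha_loss"]], p[["beta_win"]],
                         p[["beta_loss"]], p[["bias"]],
                         alpha_critic = p[["alpha_critic"]],
                         family = "actor_critic")
      }),
    stop("unknown model: ", model)
  )
}

.valuecode_models <- c("q_cs", "q_rpe", "kappa", "reinforce", "actor_critic")

# latent (unconstrained) <-> natural parameter scales
.to_natural <- function(latent, info) {
  p <- latent
  p[info$rates] <- plogis(latent[info$rates])
  names(p) <- info$names
  p
}

.to_latent <- function(natural, info) {
  l <- natural
  l[info$rates] <- qlogis(pmin(pmax(natural[info$rates], 1e-6), 1 - 1e-6))
  names(l) <- info$names
  l
}

.params_from_vector <- function(p, model) {
  info <- .model_info(model)
  info$build(p, model)
}

# ---- likelihood -----------------------------------------------------------

#' Session log-likelihood of a behavioral model
#'
#' Sums `log P(observed choice)` over completed trials, with probabilities
#' clipped to `[1e-9, 1 - 1e-9]`. No-choice trials are excluded.
#'
#' @param session a `session_data`.
#' @param params model parameters (object or named natural-scale vector).
#' @param model model name.
#' @return list with `total`, `per_choice` (mean log-likelihood per completed
#'   choice), `n_choices`, `accuracy` (fraction of trials where the model
#'   put probability > 0.5 on the observed choice; ties count 0.5), and
#'   `p_obs` (per-trial probabilities of the observed choice).
#' @export
session_log_likelihood <- function(session, params, model) {
  if (!is.list(params)) params <- .params_from_vector(params, model)
  res <- .run_model(session, params, model)
  ll <- res$ll[!is.na(res$ll)]
  stopf(length(ll) > 0, "session has no completed trials")
  p_obs <- exp(res$ll)
  acc <- mean((p_obs[!is.na(p_obs)] > 0.5) + 0.5 * (p_obs[!is.na(p_obs)] == 0.5))
  list(total = sum(ll), per_choice = mean(ll), n_choices = length(ll),
       accuracy = acc, p_obs = p_obs)
}

# negative log posterior in latent space; the prior is zero-centered
# Gaussian per latent with weakly informative per-parameter sds from the
# model registry (1 for log-odds rates, 5 for unbounded weights)
.neg_log_post <- function(latent, session, model, info, prior_sd = NULL) {
  if (is.null(prior_sd)) prior_sd <- info$prior_sd
  p <- .to_natural(latent, info)
  params <- .params_from_vector(p, model)
  ll <- tryCatch(session_log_likelihood(session, params, model)$total,
                 error = function(e) -Inf)
  lp <- sum(dnorm(latent, 0, prior_sd, log = TRUE))
  if (!is.finite(ll)) return(1e10)
  -(ll + lp)
}

#' Per-session maximum a posteriori fit
#'
#' Maximizes log-likelihood plus a standard-normal prior on the latent
#' (transformed) scale -- log-odds for rates, identity for weights -- from
#' multiple random restarts, returning point estimates on the natural scale.
#'
#' @param session a `session_data`.
#' @param model model name.
#' @param n_restarts number of optimizer restarts (first starts at 0).
#' @param prior_sd standard deviation(s) of the latent-scale prior;
#'   defaults to the registry's weakly informative values (1 for rates on
#'   the log-odds scale, 5 for unbounded weights).
#' @param seed seed for restart draws.
#' @return list of class `fit_result`: `params` (named natural vector),
#'   `params_obj`, `latent`, `log_post`, `ll`, `ll_per_choice`, `accuracy`,
#'   `n_choices`, `converged`, `model`.
#' @export
fit_session_map <- function(session, model, n_restarts = 10,
                            prior_sd = NULL, seed = 1) {
  info <- .model_info(model)
  k <- length(info$names)
  withr::with_seed(as.integer(seed), {
    starts <- rbind(rep(0, k),
                    matrix(rnorm((n_restarts - 1) * k), ncol = k))
    best <- NULL
    any_conv <- FALSE
    for (i in seq_len(nrow(starts))) {
      o <- tryCatch(
        optim(starts[i, ], .neg_log_post, session = session, model = model,
              info = info, prior_sd = prior_sd, method = "BFGS",
              control = list(maxit = 500)),
        error = function(e) NULL)
      if (is.null(o)) next
      if (o$convergence == 0) any_conv <- TRUE
      if (is.null(best) || o$value < best$value) best <- o
    }
    stopf(!is.null(best), "all optimizer restarts failed")
    p <- .to_natural(best$par, info)
    fit <- session_log_likelihood(session, .params_from_vector(p, model), model)
    structure(list(params = p, params_obj = .params_from_vector(p, model),
                   latent = best$par, log_post = -best$value,
                   ll = fit$total, ll_per_choice = fit$per_choice,
                   accuracy = fit$accuracy, n_choices = fit$n_choices,
                   converged = any_conv, model = model),
              class = "fit_result")
  })
}

#' @method print fit_result
#' @export
print.fit_result <- function(x, ...) {
  cat(sprintf("<fit_result %s> LL/choice %.4f, accuracy %.3f%s\n", x$model,
              x$ll_per_choice, x$accuracy,
              if (!x$converged) " [non-converged]" else ""))
  print(round(x$params, 4))
  invisible(x)
}

# held-out log-likelihood via blocked contiguous folds: fit on the other
# folds, score on the held-out fold, pool.
.held_out_ll <- function(session, model, n_folds = 2, n_restarts = 4,
                         seed = 1) {
  n <- nrow(session$trials)
  fold <- cut(seq_len(n), breaks = n_folds, labels = FALSE)
  total <- 0; n_ch <- 0L
  for (f in seq_len(n_folds)) {
    train <- session
    train$trials <- session$trials[fold != f, , drop = FALSE]
    test <- session
    test$trials <- session$trials[fold == f, , drop = FALSE]
    fit <- fit_session_map(train, model, n_restarts = n_restarts,
                           seed = child_seed(seed, f))
    sc <- session_log_likelihood(test, fit$params_obj, model)
    total <- total + sc$total
    n_ch <- n_ch + sc$n_choices
  }
  list(total = total, per_choice = total / n_ch, n_choices = n_ch)
}

#' Compare fitted models on a common set of sessions
#'
#' Fits every model to every session by MAP and tabulates accuracy and mean
#' log-likelihood per choice; optionally adds blocked cross-validated
#' held-out log-likelihood.
#'
#' @param sessions list of `session_data`.
#' @param models character vector of model names.
#' @param cv also compute held-out log-likelihood over blocked folds.
#' @param n_folds,n_restarts,seed fitting controls.
#' @return data frame with one row per session x model.
#' @export
compare_models <- function(sessions, models = c("q_cs", "q_rpe", "reinforce",
                                                "actor_critic"),
                           cv = FALSE, n_folds = 5, n_restarts = 10,
                           seed = 1) {
  stopf(length(sessions) >= 1, "need at least one session")
  rows <- list()
  for (s in seq_along(sessions)) {
    for (m in models) {
      fit <- fit_session_map(sessions[[s]], m, n_restarts = n_restarts,
                             seed = child_seed(seed, s * 100 + match(m, models)))
      row <- data.frame(session = s, model = m, accuracy = fit$accuracy,
                        ll_per_choice = fit$ll_per_choice,
                        stringsAsFactors = FALSE)
      if (cv) {
        ho <- .held_out_ll(sessions[[s]], m, n_folds = n_folds,
                           n_restarts = max(3, n_restarts %/% 2),
                           seed = child_seed(seed, s * 1000 + match(m, models)))
        row$ll_per_choice_cv <- ho$per_choice
      }
      rows[[length(rows) + 1L]] <- row
    }
  }
  do.call(rbind, rows)
}

# default dispersed generative parameter draws, used by the recovery and
# confusion analyses when no explicit parameter sets are supplied
.draw_gen_params <- function(model) {
  if (model %in% c("q_cs", "q_rpe", "kappa")) {
    p <- c(alpha_rew = runif(1, 0.1, 0.6), alpha_stay = runif(1, 0.1, 0.6),
           gamma_forget = runif(1, 0.05, 0.5), beta_rew = runif(1, 2, 6),
           beta_stay = runif(1, 0.5, 2), bias = rnorm(1, 0, 0.3))
    if (model == "kappa") p <- c(p, kappa = runif(1, 0.3, 1))
    p
  } else if (model == "reinforce") {
    c(alpha_win = runif(1, 0.1, 0.6), alpha_loss = runif(1, 0.1, 0.6),
      beta_win = runif(1, 1, 4), beta_loss = runif(1, 0.5, 3),
      bias = rnorm(1, 0, 0.3))
  } else {
    c(alpha_win = runif(1, 0.1, 0.6), alpha_loss = runif(1, 0.1, 0.6),
      alpha_critic = runif(1, 0.2, 0.8), beta_win = runif(1, 2, 6),
      beta_loss = runif(1, 1, 5), bias = rnorm(1, 0, 0.3))
  }
}

#' Parameter recovery analysis
#'
#' Simulates on-policy sessions at known parameters, refits by MAP, and
#' pairs true with recovered values; identifiable parameters land on the
#' diagonal.
#'
#' @param model model name.
#' @param true_params list of named natural-scale parameter vectors, or an
#'   integer number of sessions to draw dispersed parameters for.
#' @param config a [task_config()].
#' @param n_trials trials per simulated session.
#' @param seed master seed.
#' @param n_restarts optimizer restarts per refit.
#' @param session_qc apply the session-inclusion rule used for real
#'   behavior (at least 9 completed blocks and win-stay behavior: a higher
#'   repeat probability after CS+ than after CS-); parameter draws whose
#'   simulated session fails it are redrawn. Only available when
#'   `true_params` is a count.
#' @return list with `pairs` (data frame: session, parameter, true,
#'   recovered) and `correlations` (named Pearson r per parameter).
#' @export
recovery_analysis <- function(model, true_params, config = task_config(),
                              n_trials = 500, seed = 1, n_restarts = 6,
                              session_qc = FALSE) {
  draw_mode <- is.numeric(true_params) && length(true_params) == 1
  stopf(!session_qc || draw_mode,
        "session_qc requires drawing parameters internally")
  if (draw_mode) {
    n_sess <- true_params
    true_params <- withr::with_seed(child_seed(seed, 777), {
      lapply(seq_len(n_sess), function(i) .draw_gen_params(model))
    })
  }
  session_ok <- function(sess) {
    tr <- sess$trials
    n <- nrow(tr)
    stay <- c(NA, tr$choice[-1] == tr$choice[-n])
    prev_rew <- c(NA, tr$r[-n] == 1L)
    length(sess$block_boundaries) >= 9 &&
      isTRUE(mean(stay[prev_rew], na.rm = TRUE) >
               mean(stay[!prev_rew], na.rm = TRUE))
  }
  rows <- list()
  for (s in seq_along(true_params)) {
    p_true <- true_params[[s]]
    sim <- tryCatch({
      sess <- NULL
      for (attempt in 0:19) {
        params <- .params_from_vector(p_true, model)
        sess <- simulate_session(config, agent_model(params), n_trials,
                                 seed = child_seed(seed, s + 50000 * attempt))
        if (!session_qc || session_ok(sess)) break
        # redraw the ground truth: this parameter set produced behavior
        # the study's inclusion rule would discard
        p_true <- withr::with_seed(child_seed(seed, 60000 + s + 997 * attempt),
                                   .draw_gen_params(model))
      }
      fit <- fit_session_map(sess, model, n_restarts = n_restarts,
                             seed = child_seed(seed, 10000 + s))
      data.frame(session = s, parameter = names(p_true),
                 true = as.numeric(p_true),
                 recovered = as.numeric(fit$params[names(p_true)]),
                 stringsAsFactors = FALSE)
    }, error = function(e) NULL)
    if (!is.null(sim)) rows[[length(rows) + 1L]] <- sim
  }
  pairs <- do.call(rbind, rows)
  cors <- sapply(split(pairs, pairs$parameter),
                 function(d) suppressWarnings(cor(d$true, d$recovered)))
  list(pairs = pairs, correlations = cors)
}

#' Model confusion analysis
#'
#' Tests whether the model families are distinguishable: simulated choice
#' data are generated from the best model of each family — each family's
#' best-fit parameters on common reference behavior — every model is fit
#' to every simulated session, and the winner is scored by held-out
#' log-likelihood. Rows of the returned matrix (generative models) sum
#' to 1. Because the generative parameter sets are matched to the same
#' behavior, the families produce similar choice statistics and the
#' diagonal sits near chance on this task.
#'
#' @param models character vector of model names (>= 2).
#' @param config a [task_config()].
#' @param n_sessions simulated sessions per generative model.
#' @param n_trials trials per session.
#' @param seed master seed.
#' @param n_folds blocked folds for the held-out score.
#' @param n_restarts optimizer restarts per fold fit.
#' @param gen_params optional named list of natural-scale parameter vectors
#'   per model; when `NULL`, reference behavior is simulated from
#'   [reference_q_params()] and each family is fit to it to obtain its
#'   generative parameters.
#' @return list with `confusion` (row-normalized matrix of best-fit
#'   frequencies), `gen_params` (the generative parameters used), and
#'   `detail` (data frame of per-session held-out LL).
#' @export
confusion_analysis <- function(models = c("q_cs", "reinforce", "actor_critic"),
                               config = task_config(), n_sessions = 10,
                               n_trials = 300, seed = 1, n_folds = 2,
                               n_restarts = 4, gen_params = NULL) {
  stopf(length(models) >= 2, "need at least 2 models")
  if (is.null(gen_params)) {
    # reference behavior at realistic choice noise (see
    # reference_q_params()); each family's generative parameters are its
    # best fit to this common behavior, as in the published procedure
    ref_sess <- simulate_session(config, agent_model(reference_q_params()),
                                 max(600L, n_trials),
                                 seed = child_seed(seed, 555))
    gen_params <- lapply(models, function(m)
      fit_session_map(ref_sess, m, n_restarts = max(6, n_restarts),
                      seed = child_seed(seed, 556 + match(m, models)))$params)
    names(gen_params) <- models
  }
  conf <- matrix(0, length(models), length(models),
                 dimnames = list(generative = models, best_fit = models))
  detail <- list()
  for (g in seq_along(models)) {
    for (s in seq_len(n_sessions)) {
      sd0 <- child_seed(seed, g * 1000 + s)
      p_true <- gen_params[[models[g]]]
      sess <- simulate_session(config,
                               agent_model(.params_from_vector(p_true, models[g])),
                               n_trials, seed = child_seed(sd0, 1))
      ho <- sapply(seq_along(models), function(m) {
        .held_out_ll(sess, models[m], n_folds = n_folds,
                     n_restarts = n_restarts,
                     seed = child_seed(sd0, 2 + m))$total
      })
      win <- which.max(ho)
      conf[g, win] <- conf[g, win] + 1
      detail[[length(detail) + 1L]] <-
        data.frame(generative = models[g], session = s,
                   best_fit = models[win],
                   t(setNames(ho, paste0("ll_", models))))
    }
  }
  conf <- conf / rowSums(conf)
  list(confusion = conf, gen_params = gen_params,
       detail = do.call(rbind, detail))
}

#' Fit the conditioned-reinforcer value of the CS+
#'
#' Re-fits the CS-as-reward Q-learning model with the update target on CS+
#' trials *without* collected stimulation replaced by a free parameter
#' `kappa` (prior Normal(0, 1)); collected CS+ trials keep target 1 and CS-
#' trials keep target 0. `kappa` near 1 means an uncollected CS+ reinforces
#' like a collected one; near 0 means it acts like a CS-. Sessions with
#' fewer than `min_uncollected` CS+-without-stimulation trials are excluded.
#'
#' @param sessions list of `session_data`.
#' @param seed master seed.
#' @param min_uncollected inclusion threshold.
#' @param n_restarts optimizer restarts.
#' @return data frame per included session: `session`, `kappa`, `kappa_se`
#'   (Laplace standard error), `n_uncollected`, plus the other fitted
#'   parameters.
#' @export
fit_csplus_value <- function(sessions, seed = 1, min_uncollected = 5,
                             n_restarts = 8) {
  rows <- list()
  for (s in seq_along(sessions)) {
    tr <- sessions[[s]]$trials
    n_unc <- sum(tr$r == 1L & !tr$stim_collected, na.rm = TRUE)
    if (n_unc < min_uncollected) next
    fit <- fit_session_map(sessions[[s]], "kappa", n_restarts = n_restarts,
                           seed = child_seed(seed, s))
    info <- .model_info("kappa")
    h <- tryCatch(
      optimHess(fit$latent, .neg_log_post, session = sessions[[s]],
                model = "kappa", info = info),
      error = function(e) NULL)
    k_se <- NA_real_
    if (!is.null(h)) {
      cv <- tryCatch(solve(h), error = function(e) NULL)
      ki <- which(info$names == "kappa")
      if (!is.null(cv) && cv[ki, ki] > 0) k_se <- sqrt(cv[ki, ki])
    }
    rows[[length(rows) + 1L]] <- data.frame(
      session = s, kappa = fit$params[["kappa"]], kappa_se = k_se,
      n_uncollected = n_unc, t(fit$params[info$names != "kappa"]))
  }
  if (length(rows) == 0) {
    warning("no session met the minimum uncollected-CS+ count")
    return(NULL)
  }
  do.call(rbind, rows)
}
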