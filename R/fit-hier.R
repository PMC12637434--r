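# Hierarchical Bayesian fitting of the behavioral models.
#
# Three Gaussian layers on the latent (transformed) parameter scale:
#   population:  mu_k ~ N(M, tau),  log sigma_k ~ N(M, tau)
#   individual:  theta_{k,i} ~ N(mu_k, sigma_k)
#   session:     psi_{k,i,j} ~ N(theta_{k,i}, s_{k,j}),  p(s_{k,j}) flat on
#                [0, s_max]
# Sessions enter the likelihood through psi via the model's choice rule.
# Sampling is Metropolis-within-Gibbs: conjugate normal draws for mu and
# theta, random-walk Metropolis for psi (jointly per session), log s, and
# log sigma, with step sizes adapted during warmup.

#' Hierarchy specification
#'
#' @param M,tau mean and sd of the population-level priors.
#' @param s_max upper bound of the flat prior on session-level sds.
#' @return list of class `hierarchy_spec`.
#' @export
hierarchy_spec <- function(M = 0, tau = 1, s_max = 5) {
  structure(list(M = M, tau = tau, s_max = s_max), class = "hierarchy_spec")
}

# split-Rhat for one parameter: draws is an iterations x chains matrix
.split_rhat <- function(draws) {
  n <- nrow(draws)
  half <- n %/% 2L
  sub <- cbind(draws[seq_len(half), , drop = FALSE],
               draws[(n - half + 1L):n, , drop = FALSE])
  m <- ncol(sub); nn <- nrow(sub)
  means <- colMeans(sub)
  vars <- apply(sub, 2, var)
  B <- nn * var(means)
  W <- mean(vars)
  if (W == 0) return(1)
  sqrt(((nn - 1) / nn * W + B / nn) / W)
}

#' Hierarchical Bayesian fit across subjects and sessions
#'
#' Fits a behavioral model to many sessions at once with partial pooling at
#' the population, subject, and session levels, using a
#' Metropolis-within-Gibbs sampler on the latent parameter scale. Point
#' estimates are posterior medians of the session-level parameters mapped to
#' the natural scale. Convergence is summarized by split-Rhat across chains
#' (all below 1.01 is the usual bar; at the short default chain lengths a
#' slightly looser bar can be appropriate).
#'
#' @param sessions list of `session_data`.
#' @param subject integer/character vector assigning each session to a
#'   subject.
#' @param model model name.
#' @param spec a [hierarchy_spec()].
#' @param n_chains,n_iter,warmup MCMC settings; defaults are desk-scale
#'   (2 chains of 600 with 200 warmup). The heavier published-style setting
#'   (4 chains of 1850 with 350 warmup) is available by passing those values.
#' @param seed master seed.
#' @return list with `session_params` (data frame of posterior-median
#'   natural-scale parameters per session), `population` (posterior medians
#'   of `mu` and `sigma` per parameter), `rhat` (named vector), `accept`
#'   (mean MH acceptance per block), and `draws` (session-level latent
#'   draws, iterations x chains x sessions x parameters).
#' @export
fit_hierarchical <- function(sessions, subject, model,
                             spec = hierarchy_spec(),
                             n_chains = 2, n_iter = 600, warmup = 200,
                             seed = 1) {
  stopf(length(sessions) == length(subject),
        "`subject` must have one entry per session")
  info <- .model_info(model)
  K <- length(info$names)
  J <- length(sessions)
  subj <- as.integer(factor(subject))
  I <- max(subj)

  keep <- n_iter - warmup
  draws <- array(NA_real_, c(keep, n_chains, J, K))
  mu_draws <- array(NA_real_, c(keep, n_chains, K))
  sig_draws <- array(NA_real_, c(keep, n_chains, K))
  acc_psi <- 0; try_psi <- 0

  for (ch in seq_len(n_chains)) {
    withr::with_seed(child_seed(seed, ch), {
      mu <- rnorm(K, 0, 0.1)
      log_sigma <- rnorm(K, -1, 0.1)
      theta <- matrix(rnorm(I * K, 0, 0.1), I, K)
      psi <- matrix(rnorm(J * K, 0, 0.1), J, K)
      s <- matrix(0.5, J, K)          # session-level sds s_{k,j}
      step_psi <- rep(0.15, J)
      step_s <- 0.3
      step_sig <- 0.3
      ll_cur <- vapply(seq_len(J), function(j) {
        p <- .to_natural(psi[j, ], info)
        session_log_likelihood(sessions[[j]],
                               .params_from_vector(p, model), model)$total
      }, numeric(1))

      for (it in seq_len(n_iter)) {
        # -- psi | rest : joint RW-MH per session
        for (j in seq_len(J)) {
          prop <- psi[j, ] + rnorm(K, 0, step_psi[j])
          p_nat <- .to_natural(prop, info)
          ll_new <- tryCatch(
            session_log_likelihood(sessions[[j]],
                                   .params_from_vector(p_nat, model),
                                   model)$total,
            error = function(e) -Inf)
          lp_new <- sum(dnorm(prop, theta[subj[j], ], s[j, ], log = TRUE))
          lp_old <- sum(dnorm(psi[j, ], theta[subj[j], ], s[j, ], log = TRUE))
          try_psi <- try_psi + 1
          if (is.finite(ll_new) &&
              log(runif(1)) < (ll_new + lp_new) - (ll_cur[j] + lp_old)) {
            psi[j, ] <- prop; ll_cur[j] <- ll_new
            acc_psi <- acc_psi + 1
            if (it <= warmup) step_psi[j] <- step_psi[j] * 1.05
          } else if (it <= warmup) step_psi[j] <- step_psi[j] * 0.97
        }
        # -- s | psi, theta : RW-MH on log s, flat prior on [0, s_max]
        for (j in seq_len(J)) {
          prop <- s[j, ] * exp(rnorm(K, 0, step_s))
          ok <- prop <= spec$s_max
          for (k in which(ok)) {
            num <- dnorm(psi[j, k], theta[subj[j], k], prop[k], log = TRUE) +
              log(prop[k])      # Jacobian of the log transform
            den <- dnorm(psi[j, k], theta[subj[j], k], s[j, k], log = TRUE) +
              log(s[j, k])
            if (log(runif(1)) < num - den) s[j, k] <- prop[k]
          }
        }
        # -- theta | mu, sigma, psi, s : conjugate normal
        sigma <- exp(log_sigma)
        for (i in seq_len(I)) {
          js <- which(subj == i)
          for (k in seq_len(K)) {
            prec <- 1 / sigma[k]^2 + sum(1 / s[js, k]^2)
            mean_k <- (mu[k] / sigma[k]^2 + sum(psi[js, k] / s[js, k]^2)) / prec
            theta[i, k] <- rnorm(1, mean_k, sqrt(1 / prec))
          }
        }
        # -- mu | theta, sigma : conjugate normal with prior N(M, tau)
        for (k in seq_len(K)) {
          prec <- 1 / spec$tau^2 + I / sigma[k]^2
          mean_k <- (spec$M / spec$tau^2 + sum(theta[, k]) / sigma[k]^2) / prec
          mu[k] <- rnorm(1, mean_k, sqrt(1 / prec))
        }
        # -- log sigma : RW-MH with prior N(M, tau)
        for (k in seq_len(K)) {
          prop <- log_sigma[k] + rnorm(1, 0, step_sig)
          num <- sum(dnorm(theta[, k], mu[k], exp(prop), log = TRUE)) +
            dnorm(prop, spec$M, spec$tau, log = TRUE)
          den <- sum(dnorm(theta[, k], mu[k], exp(log_sigma[k]), log = TRUE)) +
            dnorm(log_sigma[k], spec$M, spec$tau, log = TRUE)
          if (log(runif(1)) < num - den) log_sigma[k] <- prop
        }
        if (it > warmup) {
          draws[it - warmup, ch, , ] <- psi
          mu_draws[it - warmup, ch, ] <- mu
          sig_draws[it - warmup, ch, ] <- exp(log_sigma)
        }
      }
    })
  }

  # posterior medians on the natural scale per session
  sess_rows <- lapply(seq_len(J), function(j) {
    med <- apply(draws[, , j, , drop = FALSE], 4, median)
    p <- .to_natural(med, info)
    data.frame(session = j, subject = subject[j], t(p))
  })
  rhat <- numeric(0)
  for (k in seq_len(K)) {
    rhat[paste0("mu_", info$names[k])] <- .split_rhat(mu_draws[, , k])
    for (j in seq_len(J)) {
      rhat[paste0("psi_", info$names[k], "_s", j)] <-
        .split_rhat(draws[, , j, k])
    }
  }
  list(session_params = do.call(rbind, sess_rows),
       population = data.frame(
         parameter = info$names,
         mu = apply(mu_draws, 3, median),
         sigma = apply(sig_draws, 3, median)),
       rhat = rhat,
       accept = acc_psi / try_psi,
       draws = draws)
}
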