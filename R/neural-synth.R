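#' Ground-truth synthetic neuron
#'
#' Defines a neuron whose activity follows the bilinear generative form: a
#' baseline plus event kernels scaled per trial by gains that are linear in
#' the trial variables, with Gaussian noise (for exact-recovery tests) or a
#' Poisson log-link (for count realism). Kernels are drawn in the same
#' raised-cosine span the encoding model uses, so the ground truth lies
#' exactly in the model span, and unit-normalized to match the fitted
#' kernels' scale convention.
#'
#' @param design an [build_design_matrix()] result (supplies the bases).
#' @param gain_offset named numeric vector, one multiplicative offset per
#'   event (amplitude of the event response).
#' @param gain_coef matrix (events x variables, dimnames required) of value
#'   gain coefficients; `NULL` for a value-blind neuron.
#' @param baseline additive baseline of the latent signal (z-units in
#'   Gaussian mode).
#' @param noise_sd Gaussian noise sd.
#' @param mode `"gaussian"` or `"poisson_log_link"`.
#' @param poisson_a,poisson_b intensity mapping `rate = exp(a + b * signal)`
#'   per bin in Poisson mode.
#' @param region,hemisphere metadata labels.
#' @param seed seed for the random kernel shapes.
#' @return list of class `ground_truth_neuron`.
#' @export
ground_truth_neuron <- function(design,
                                gain_offset = setNames(rep(1, 6), .event_names),
                                gain_coef = NULL,
                                baseline = 0, noise_sd = 1,
                                mode = c("gaussian", "poisson_log_link"),
                                poisson_a = log(0.5), poisson_b = 1,
                                region = "CP", hemisphere = "left",
                                seed = 1) {
  mode <- match.arg(mode)
  stopf(!(mode == "poisson_log_link") || poisson_b >= 0,
        "poisson_b must be nonnegative")
  kernel_coef <- withr::with_seed(as.integer(seed), {
    lapply(.event_names, function(e) {
      B <- design$bases[[e]]
      co <- rnorm(B$n_dof)
      kv <- B$matrix %*% co
      co / sqrt(sum(kv^2))                     # unit-norm kernel
    })
  })
  names(kernel_coef) <- .event_names
  if (!is.null(gain_coef)) {
    stopf(is.matrix(gain_coef) && nrow(gain_coef) == length(.event_names),
          "gain_coef must be an events x variables matrix")
  }
  structure(list(kernel_coef = kernel_coef, gain_offset = gain_offset,
                 gain_coef = gain_coef, baseline = baseline,
                 noise_sd = noise_sd, mode = mode,
                 poisson_a = poisson_a, poisson_b = poisson_b,
                 region = region, hemisphere = hemisphere),
            class = "ground_truth_neuron")
}

#' Generate a synthetic neuron's binned activity
#'
#' Builds the latent signal through the same design-matrix code path the
#' encoding model fits, guaranteeing that recovery is achievable in the
#' noiseless Gaussian limit, and adds noise according to the neuron's mode.
#'
#' @param neuron a [ground_truth_neuron()].
#' @param design an [build_design_matrix()] result.
#' @param U trial-variable matrix (included trials x variables) matching
#'   `neuron$gain_coef` columns; may be `NULL` for value-blind neurons.
#' @param seed RNG seed for the noise.
#' @return list: `counts` (activity per grid row; Gaussian mode returns the
#'   continuous signal + noise, Poisson mode integer counts), `signal`
#'   (noiseless latent), `gains` (trial x event matrix).
#' @export
generate_neuron_spikes <- function(neuron, design, U = NULL, seed = 1) {
  tl <- design$timeline
  n_trial <- max(tl$row_trial)
  G <- matrix(rep(neuron$gain_offset, each = n_trial), n_trial,
              length(.event_names))
  if (!is.null(neuron$gain_coef)) {
    stopf(!is.null(U) && all(colnames(neuron$gain_coef) %in% colnames(U)),
          "U must provide the variables named in gain_coef")
    G <- G + as.matrix(U[, colnames(neuron$gain_coef), drop = FALSE]) %*%
      t(neuron$gain_coef)
  }
  signal <- rep(neuron$baseline, tl$n_rows)
  for (i in seq_along(.event_names)) {
    e <- .event_names[i]
    zi <- as.numeric(design$X[, design$blocks[[e]], drop = FALSE] %*%
                       neuron$kernel_coef[[e]])
    signal <- signal + G[tl$row_trial, i] * zi
  }
  withr::with_seed(as.integer(seed), {
    counts <- if (neuron$mode == "gaussian") {
      signal + neuron$noise_sd * rnorm(length(signal))
    } else {
      rpois(length(signal),
            exp(neuron$poisson_a + neuron$poisson_b * signal))
    }
    list(counts = counts, signal = signal, gains = G)
  })
}

#' Generate a labeled synthetic population
#'
#' Mixes three neuron types in given fractions: value-coding neurons (event
#' kernels plus one planted gain of known sign on a known event and
#' variable), event-only neurons (kernels but value-blind), and silent
#' neurons (pure noise). Ground-truth labels are returned for downstream
#' calibration and recovery checks.
#'
#' @param n_neurons population size.
#' @param mix named fractions `c(value = , event = , silent = )`, summing
#'   to 1.
#' @param design an [build_design_matrix()] result.
#' @param U trial-variable matrix for the value-coding neurons (detrended
#'   upstream if the analysis will detrend).
#' @param gain_strength absolute value of the planted gain coefficient.
#' @param gain_events events eligible to carry the planted gain.
#' @param noise_sd Gaussian noise sd.
#' @param mode noise mode, see [ground_truth_neuron()].
#' @param seed master seed.
#' @return list: `counts` (neurons x grid rows matrix), `meta` (data frame:
#'   neuron, type, region, hemisphere, gain_event, gain_var, gain_coef),
#'   `neurons` (list of ground-truth neurons).
#' @export
generate_population <- function(n_neurons, mix = c(value = 0.3, event = 0.6,
                                                   silent = 0.1),
                                design, U = NULL, gain_strength = 0.5,
                                gain_events = c("go", "cs_plus", "cs_minus"),
                                noise_sd = 1, mode = "gaussian", seed = 1) {
  stopf(n_neurons >= 1, "n_neurons must be >= 1")
  stopf(abs(sum(mix) - 1) < 1e-9, "mixture fractions must sum to 1")
  n_val <- round(n_neurons * mix[["value"]])
  n_ev <- round(n_neurons * mix[["event"]])
  n_sil <- n_neurons - n_val - n_ev
  types <- c(rep("value", n_val), rep("event", n_ev), rep("silent", n_sil))
  counts <- matrix(NA_real_, n_neurons, design$timeline$n_rows)
  meta <- data.frame(neuron = seq_len(n_neurons), type = types,
                     region = "CP", hemisphere = "left",
                     gain_event = NA_character_, gain_var = NA_character_,
                     gain_coef = NA_real_, stringsAsFactors = FALSE)
  neurons <- vector("list", n_neurons)
  for (i in seq_len(n_neurons)) {
    sd_i <- child_seed(seed, i)
    if (types[i] == "silent") {
      nr <- ground_truth_neuron(design, gain_offset = setNames(rep(0, 6),
                                                               .event_names),
                                noise_sd = noise_sd, mode = mode, seed = sd_i)
    } else if (types[i] == "event") {
      nr <- ground_truth_neuron(design, noise_sd = noise_sd, mode = mode,
                                seed = sd_i)
    } else {
      stopf(!is.null(U), "value-coding neurons require U")
      pick <- withr::with_seed(child_seed(sd_i, 2), {
        list(event = sample(gain_events, 1),
             var = sample(colnames(U), 1),
             sign = sample(c(-1, 1), 1))
      })
      gc <- matrix(0, length(.event_names), ncol(U),
                   dimnames = list(.event_names, colnames(U)))
      gc[pick$event, pick$var] <- pick$sign * gain_strength
      nr <- ground_truth_neuron(design, gain_coef = gc, noise_sd = noise_sd,
                                mode = mode, seed = sd_i)
      meta$gain_event[i] <- pick$event
      meta$gain_var[i] <- pick$var
      meta$gain_coef[i] <- pick$sign * gain_strength
    }
    neurons[[i]] <- nr
    counts[i, ] <- generate_neuron_spikes(nr, design, U,
                                          seed = child_seed(sd_i, 3))$counts
  }
  list(counts = counts, meta = meta, neurons = neurons)
}

#' Synthesize a wheel position trace with known movement onsets
#'
#' Produces a 1 kHz position trace (cm) that is flat (small smooth noise)
#' between movements and executes a smoothstep displacement at each trial's
#' movement onset (positive for Right/counterclockwise choices, negative for
#' Left), so the true onsets are known exactly for validating the onset
#' detector.
#'
#' @param session a `session_data`.
#' @param seed RNG seed.
#' @param rate samples per second.
#' @param amplitude displacement per movement (cm).
#' @param noise_sd sd of the smoothed positional jitter (cm).
#' @return list: `time`, `position`, `onsets` (true movement-onset times,
#'   one per completed trial).
#' @export
synthesize_wheel_trace <- function(session, seed = 1, rate = 1000,
                                   amplitude = 1.2, noise_sd = 0.002) {
  tr <- session$trials
  done <- !is.na(tr$choice)
  dur_total <- max(tr$t_outcome, na.rm = TRUE) + 2
  tm <- seq(0, dur_total, by = 1 / rate)
  pos <- withr::with_seed(as.integer(seed), {
    moving_average(rnorm(length(tm), 0, noise_sd), 201L)
  })
  for (i in which(done)) {
    on <- tr$t_move[i]
    mdur <- max(tr$t_outcome[i] - tr$t_move[i], 0.05)
    sgn <- if (tr$choice[i] == "R") 1 else -1
    u <- (tm - on) / mdur
    ramp <- ifelse(u <= 0, 0, ifelse(u >= 1, 1, 3 * u^2 - 2 * u^3))
    pos <- pos + sgn * amplitude * ramp
  }
  list(time = tm, position = pos, onsets = tr$t_move[done])
}
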