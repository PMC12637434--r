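#' Configuration of the spike-train encoding model
#'
#' Defines the 10 ms binning grid, the per-event kernel windows (seconds
#' relative to the event), the raised-cosine basis resolution (one cosine per
#' 25 ms of kernel span), the log-spaced spike-history basis, and the
#' penalty search grid. The per-trial grid runs from `grid_pad[1]` s before
#' the go cue to `grid_pad[2]` s after the outcome so that every kernel
#' window fits inside it.
#'
#' @param bin bin width in seconds.
#' @param spans named list of kernel windows, seconds relative to each event:
#'   go cue, left/right movement onset, CS+, stimulation onset, CS-.
#' @param basis_spacing seconds of kernel span per cosine basis function.
#' @param history_n,history_range spike-history basis: number of cosines and
#'   the (past) time range they tile, log-spaced and strictly causal.
#' @param grid_pad seconds of grid before the go cue / after the outcome.
#' @param lambda_grid penalty grid for both the lasso kernel stage and the
#'   ridge gain stage (251 log-spaced values spanning 1e-5 to 1e5).
#' @param n_folds cross-validation folds, stratified by block side, choice,
#'   and outcome.
#' @param max_iter,tol bilinear alternation: iteration cap and the absolute
#'   per-coefficient change that must hold for three consecutive iterations.
#' @return list of class `encoding_config`.
#' @export
encoding_config <- function(bin = 0.01,
                            spans = list(go = c(0, 1),
                                         move_l = c(-0.5, 0.5),
                                         move_r = c(-0.5, 0.5),
                                         cs_plus = c(0, 2),
                                         stim = c(0, 2),
                                         cs_minus = c(0, 2)),
                            basis_spacing = 0.025,
                            history_n = 10, history_range = c(0.01, 1),
                            grid_pad = c(0.6, 2.0),
                            lambda_grid = 10^seq(-5, 5, length.out = 251),
                            n_folds = 5,
                            max_iter = 100, tol = 1e-3) {
  stopf(bin > 0, "bin width must be positive")
  structure(list(bin = bin, spans = spans, basis_spacing = basis_spacing,
                 history_n = history_n, history_range = history_range,
                 grid_pad = grid_pad, lambda_grid = lambda_grid,
                 n_folds = n_folds, max_iter = max_iter, tol = tol),
            class = "encoding_config")
}
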