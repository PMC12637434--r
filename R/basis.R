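#' Raised-cosine basis sets
#'
#' `kind = "linear_cosine"` tiles a kernel window with raised cosines at one
#' cosine per `spacing` seconds of span (25 ms by default): centers are
#' evenly spaced `spacing` apart and each cosine has half-period `2 *
#' spacing`, so the pointwise sum is constant away from the window edges
#' (partition-of-unity tiling). `kind = "log_cosine_history"` places
#' `n` cosines with centers evenly spaced in warped time `log(t + psi)` over
#' `range` (10 cosines from 10 ms to 1 s by default), strictly causal, for
#' spike-history effects.
#'
#' @param kind basis family.
#' @param span numeric window `c(t0, t1)` in seconds relative to the event
#'   (linear basis only).
#' @param bin bin width in seconds.
#' @param spacing seconds per cosine (linear basis).
#' @param n,range history basis: number of cosines and time range.
#' @param psi warp offset for the log time axis.
#' @return list of class `basis_set`: `kind`, `times` (bin centers relative
#'   to the event; strictly positive lags for the history basis), `matrix`
#'   (times x basis), `n_dof`, `span`.
#' @export
make_basis <- function(kind = c("linear_cosine", "log_cosine_history"),
                       span = c(0, 1), bin = 0.01, spacing = 0.025,
                       n = 10, range = c(0.01, 1), psi = 0.005) {
  kind <- match.arg(kind)
  if (kind == "linear_cosine") {
    len <- span[2] - span[1]
    stopf(len > 0, "span must have positive length")
    n_dof <- as.integer(ceiling(round(len / spacing, 9)))
    n_bins <- as.integer(round(len / bin))
    times <- span[1] + (seq_len(n_bins) - 0.5) * bin
    d <- spacing
    centers <- span[1] + (seq_len(n_dof) - 0.5) * d
    B <- vapply(centers, function(cj) {
      u <- (times - cj) / (2 * d)
      ifelse(abs(u) < 1, 0.5 * (1 + cos(pi * u)), 0)
    }, numeric(length(times)))
  } else {
    # lags start one bin in the past so the current bin never predicts itself
    max_lag <- range[2] + 4 * bin
    lags <- seq(bin, max_lag, by = bin)
    u <- log(lags + psi)
    u1 <- log(range[1] + psi); u2 <- log(range[2] + psi)
    centers <- seq(u1, u2, length.out = n)
    du <- if (n > 1) centers[2] - centers[1] else (u2 - u1 + 1)
    B <- vapply(centers, function(cj) {
      z <- (u - cj) / (2 * du)
      ifelse(abs(z) < 1, 0.5 * (1 + cos(pi * z)), 0)
    }, numeric(length(lags)))
    # trim trailing all-zero lags
    nz <- which(rowSums(B) > 0)
    B <- B[seq_len(max(nz)), , drop = FALSE]
    times <- lags[seq_len(max(nz))]
    n_dof <- n
    span <- range
  }
  structure(list(kind = kind, times = times, matrix = B,
                 n_dof = as.integer(n_dof), span = span, bin = bin),
            class = "basis_set")
}
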