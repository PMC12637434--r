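#' Logistic (sigmoid) function
#'
#' @param x numeric vector.
#' @return `1 / (1 + exp(-x))`.
#' @export
sigmoid <- function(x) plogis(x)

# Clip probabilities away from 0/1 before taking logs.
clip_prob <- function(p, eps = 1e-9) pmin(pmax(p, eps), 1 - eps)

# Stop unless a condition holds, with a formatted message.
stopf <- function(cond, fmt, ...) {
  if (!cond) stop(sprintf(fmt, ...), call. = FALSE)
}

# Derive a reproducible child seed from a parent seed and an index.
# Kept well below 2^31 so it is always a valid R integer seed.
child_seed <- function(seed, i) {
  as.integer((as.numeric(seed) * 1103L + as.numeric(i) * 7919L) %% 2147483629)
}

# Centered moving average with window of `k` samples (k odd preferred).
moving_average <- function(x, k) {
  if (k <= 1L) return(x)
  f <- rep(1 / k, k)
  y <- stats::filter(x, f, sides = 2)
  # edges: shrink the window rather than dropping to NA
  n <- length(x)
  half <- (k - 1L) %/% 2L
  idx <- which(is.na(y))
  for (i in idx) {
    lo <- max(1L, i - half)
    hi <- min(n, i + half)
    y[i] <- mean(x[lo:hi])
  }
  as.numeric(y)
}
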