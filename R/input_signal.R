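#' Generate the synthetic visual-input signal
#'
#' Realization of the package's fixed stable AR(10) process standing in for a
#' V1 signal recorded during visual spatial attention: five complex pole
#' pairs give a 1/f-like spectral decay with an alpha-band (8-12 Hz)
#' resonance. The output is scaled to unit stationary variance.
#'
#' @param n_samples number of samples to generate
#' @param seed optional integer seed for the innovation draw
#' @param innovations optional numeric vector of length `n_samples` used as
#'   the innovation sequence (no burn-in, zero initial state); overrides
#'   `seed`. Useful for deterministic checks.
#' @param burn_in samples discarded at the start when innovations are drawn
#'   internally, so the output is approximately stationary
#' @return numeric vector of length `n_samples`
#' @examples
#' x <- generate_input_signal(1024, seed = 1)
#' @export
generate_input_signal <- function(n_samples, seed = NULL, innovations = NULL,
                                  burn_in = 1000L) {
  if (!is.numeric(n_samples) || length(n_samples) != 1 || n_samples < 1) {
    stop("n_samples must be a positive integer")
  }
  n_samples <- as.integer(n_samples)
  phi <- input_ar_coefficients()
  if (is.null(innovations)) {
    if (!is.null(seed)) set.seed(seed)
    e <- rnorm(n_samples + burn_in)
    y <- stats::filter(e, phi, method = "recursive")
    y <- as.numeric(y)[(burn_in + 1):(burn_in + n_samples)]
  } else {
    stopifnot(length(innovations) == n_samples)
    y <- as.numeric(stats::filter(innovations, phi, method = "recursive"))
  }
  y / sqrt(input_ar_variance(phi))
}

# stationary variance of the AR process for unit innovation variance,
# via numerical integration of the spectral density
input_ar_variance <- function(phi) {
  f <- seq(0, 0.5, length.out = 16385L)
  k <- seq_along(phi)
  H2 <- vapply(f, function(ff) {
    1 / Mod(1 - sum(phi * exp(-2i * pi * ff * k)))^2
  }, numeric(1))
  # trapezoid over [0, 0.5], doubled for the symmetric half
  2 * (sum(H2) - 0.5 * (H2[1] + H2[length(H2)])) * (0.5 / (length(f) - 1))
}

#' Select a stationary (M)AR model order by Schwarz's Bayesian Criterion
#'
#' Fits stationary autoregressive models of orders `1..max_order` by least
#' squares on a common effective sample (the first `max_order` samples are
#' used as presample for every order, so criteria are comparable) and returns
#' the order minimizing
#' `SBC(p) = N * log(det(Sigma_p)) + p * m^2 * log(N)`,
#' with `Sigma_p` the residual covariance and `m` the channel count.
#'
#' @param series numeric vector, or m x N matrix (channels in rows)
#' @param max_order largest order searched
#' @return the selected order (integer); the full criterion curve is attached
#'   as attribute `"sbc"`.
#' @export
sbc_order_select <- function(series, max_order) {
  if (is.vector(series)) series <- matrix(series, nrow = 1)
  m <- nrow(series); N_tot <- ncol(series)
  stopifnot(max_order >= 1)
  if (N_tot <= max_order * m + max_order) {
    stop("series too short for max_order = ", max_order)
  }
  sds <- apply(series, 1, sd)
  if (any(sds == 0 | !is.finite(sds))) {
    bad <- which(sds == 0 | !is.finite(sds))[1]
    stop("degenerate (constant or non-finite) series in channel ", bad)
  }
  N <- N_tot - max_order
  Y <- t(series[, (max_order + 1):N_tot, drop = FALSE])   # N x m
  X <- matrix(0, N, m * max_order)
  for (k in seq_len(max_order)) {
    X[, (k - 1) * m + seq_len(m)] <-
      t(series[, (max_order + 1 - k):(N_tot - k), drop = FALSE])
  }
  sbc <- vapply(seq_len(max_order), function(p) {
    Xp <- X[, seq_len(m * p), drop = FALSE]
    fit <- stats::lm.fit(Xp, Y)
    res <- as.matrix(fit$residuals)
    Sigma <- crossprod(res) / N
    val <- determinant(Sigma, logarithm = TRUE)
    if (val$sign <= 0) return(Inf)
    N * as.numeric(val$modulus) + p * m^2 * log(N)
  }, numeric(1))
  out <- which.min(sbc)
  attr(out, "sbc") <- sbc
  out
}
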