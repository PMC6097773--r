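#' Estimate the diagonal sensor-noise covariance from baseline data
#'
#' Per-sensor variance over all baseline samples and trials; off-diagonal
#' structure is discarded (uncorrelated measurement-noise model). Diagonal
#' loading adds `reg_factor` times the mean diagonal to every variance.
#'
#' @param scalp_trials a sensor-space `trial_tensor`
#' @param baseline_window integer sample indices of the baseline (default:
#'   all samples before time 0)
#' @param reg_factor diagonal-loading factor (default 0.1)
#' @return object of class `noise_cov`: list with `variances` (per sensor)
#'   and `reg_factor`
#' @export
estimate_noise_covariance <- function(scalp_trials, baseline_window = NULL,
                                      reg_factor = 0.1) {
  stopifnot(inherits(scalp_trials, "trial_tensor"))
  d <- dim(scalp_trials$data)
  if (is.null(baseline_window)) {
    t_ms <- scalp_trials$t0_ms + (seq_len(d[3]) - 1) / scalp_trials$fs * 1000
    baseline_window <- which(t_ms < 0)
  }
  if (length(baseline_window) == 0) stop("empty baseline window")
  if (any(baseline_window < 1 | baseline_window > d[3])) {
    stop("baseline window outside trial extent")
  }
  x <- scalp_trials$data[, , baseline_window, drop = FALSE]
  v <- apply(x, 2, function(z) mean(z^2) - mean(z)^2)
  v <- v + reg_factor * mean(v)
  if (any(v <= 0)) stop("non-positive baseline variance; cannot regularize")
  structure(list(variances = v, reg_factor = reg_factor),
            class = "noise_cov")
}

#' @export
as.matrix.noise_cov <- function(x, ...) diag(x$variances)

#' Compute the shared sLORETA inversion kernel
#'
#' Minimum-norm kernel `K_mne = G' (G G' + lambda C)^-1` with
#' `lambda = 1 / scalp_snr^2` and `C` the diagonal noise covariance scaled to
#' unit mean diagonal (the lead field is unit-normalized by construction, so
#' `lambda` acts as a relative regularizer). sLORETA standardization divides
#' each vertex estimate by the square root of the corresponding diagonal
#' element of the model resolution `K_mne G` (fixed-orientation case). A
#' pseudoinverse is used if the regularized Gram matrix is numerically
#' singular.
#'
#' @param leadfield a `lead_field`
#' @param noisecov a `noise_cov`, or `NULL` for an identity covariance
#' @param scalp_snr signal-to-noise ratio of the data (> 0); the
#'   regularization is `lambda = 1/scalp_snr^2`
#' @return object of class `inversion_kernel`: list with `K` (V x E),
#'   `lambda`, and the per-vertex `standardization` factors applied
#' @export
compute_sloreta_kernel <- function(leadfield, noisecov, scalp_snr) {
  stopifnot(inherits(leadfield, "lead_field"), scalp_snr > 0)
  G <- leadfield$G
  E <- nrow(G)
  lambda <- 1 / scalp_snr^2
  cvar <- if (is.null(noisecov)) rep(1, E) else noisecov$variances
  stopifnot(length(cvar) == E)
  cvar <- cvar / mean(cvar)                  # unit mean diagonal
  gram <- tcrossprod(G) + lambda * diag(cvar)
  Kmne <- tryCatch(t(solve(gram, G)),
                   error = function(e) t(crossprod(MASS_ginv(gram), G)))
  # resolution diagonal: diag(Kmne %*% G)
  rdiag <- rowSums(Kmne * t(G))
  rdiag <- pmax(rdiag, .Machine$double.eps)
  std <- 1 / sqrt(rdiag)
  structure(list(K = Kmne * std, lambda = lambda, standardization = std),
            class = "inversion_kernel")
}

# minimal Moore-Penrose pseudoinverse (symmetric case)
MASS_ginv <- function(X, tol = sqrt(.Machine$double.eps)) {
  s <- svd(X)
  pos <- s$d > tol * s$d[1]
  s$v[, pos, drop = FALSE] %*% (t(s$u[, pos, drop = FALSE]) / s$d[pos])
}

#' Apply an inversion kernel to sensor trials
#'
#' Linear application of the shared kernel to every trial.
#'
#' @param kernel an `inversion_kernel`
#' @param scalp_trials a sensor-space `trial_tensor`
#' @param rows optional subset of source rows (vertex indices) to compute
#' @return a `trial_tensor` over (selected) source vertices
#' @export
apply_kernel <- function(kernel, scalp_trials, rows = NULL) {
  stopifnot(inherits(kernel, "inversion_kernel"),
            inherits(scalp_trials, "trial_tensor"))
  K <- kernel$K
  if (!is.null(rows)) K <- K[rows, , drop = FALSE]
  d <- dim(scalp_trials$data)
  if (ncol(K) != d[2]) stop("kernel/sensor dimension mismatch")
  out <- array(0, dim = c(d[1], nrow(K), d[3]))
  for (r in seq_len(d[1])) {
    out[r, , ] <- K %*% scalp_trials$data[r, , ]
  }
  trial_tensor(out, fs = scalp_trials$fs, t0_ms = scalp_trials$t0_ms,
               channels = if (is.null(rows)) sprintf("v%d", seq_len(nrow(K)))
                          else sprintf("v%d", rows))
}

#' Resolution matrix of an inverse solution
#'
#' `R = K G`; element `R[v, w]` is the response at vertex `v` to unit
#' activity at vertex `w`. Columns are outflow cross-talk functions (CTF) of
#' a source, rows are inflow CTFs of an estimate.
#'
#' @param kernel an `inversion_kernel`
#' @param leadfield a `lead_field`
#' @return V x V matrix
#' @export
resolution_matrix <- function(kernel, leadfield) {
  if (ncol(kernel$K) != nrow(leadfield$G)) {
    stop("kernel/lead-field dimension mismatch")
  }
  kernel$K %*% leadfield$G
}
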