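#' Frequency-domain transform of MVAR coefficients
#'
#' Computes the complex matrix
#' `Abar(f, n) = I - sum_k A_k(n) exp(-i 2 pi (f/fs) k)`
#' for every requested frequency and time bin. This reference implementation
#' is plain R; the fast path used by [pdc_from_coeffs()] is compiled.
#'
#' @param coeffs m x m x p x N coefficient tensor (`A[i,j,k,n]`), or an
#'   `mvar_traj` / `tvmvar_params`
#' @param freqs_hz frequencies in Hz, inside `(0, fs/2]`
#' @param fs sampling frequency in Hz (taken from the object if available)
#' @return complex array (m, m, F, N)
#' @export
spectral_transform <- function(coeffs, freqs_hz, fs = NULL) {
  cf <- resolve_coeffs(coeffs, fs)
  A <- cf$A; fs <- cf$fs
  check_freqs(freqs_hz, fs)
  d <- dim(A)
  m <- d[1]; p <- d[3]; N <- d[4]
  out <- array(0i, dim = c(m, m, length(freqs_hz), N))
  I_m <- diag(m)
  for (n in seq_len(N)) {
    for (fi in seq_along(freqs_hz)) {
      ph <- exp(-2i * pi * (freqs_hz[fi] / fs) * seq_len(p))
      Ab <- I_m + 0i
      for (k in seq_len(p)) Ab <- Ab - A[, , k, n] * ph[k]
      out[, , fi, n] <- Ab
    }
  }
  out
}

#' Squared partial directed coherence from a spectral transform
#'
#' `|pi_ij(f,n)|^2 = |Abar_ij|^2 / sum_r |Abar_rj|^2`: the column-normalized
#' squared outflow from sender `j` to receiver `i`. By construction the
#' squared values sum to 1 over receivers for every (sender, frequency,
#' time).
#'
#' @param Abar complex array (m, m, F, N) from [spectral_transform()]
#' @return numeric array (m, m, F, N) of squared PDC values
#' @export
squared_pdc <- function(Abar) {
  stopifnot(length(dim(Abar)) == 4)
  num <- Mod(Abar)^2
  denom <- apply(num, c(2, 3, 4), sum)
  if (any(denom <= 0)) {
    bad <- which(denom <= 0, arr.ind = TRUE)[1, ]
    stop("zero PDC denominator at sender ", bad[1], ", frequency index ",
         bad[2], ", time bin ", bad[3])
  }
  sweep(num, c(2, 3, 4), denom, "/")
}

#' Squared time-varying PDC of a coefficient trajectory (fast path)
#'
#' @param coeffs m x m x p x N tensor, `mvar_traj` or `tvmvar_params`
#' @param freqs_hz frequency grid in Hz (default 1-40 Hz in 1 Hz steps)
#' @param fs sampling frequency in Hz
#' @return object of class `pdc_tensor`: list with `values`
#'   (receiver x sender x frequency x time), `freqs_hz`, `fs`,
#'   `normalized = TRUE`
#' @export
pdc_from_coeffs <- function(coeffs, freqs_hz = 1:40, fs = NULL) {
  cf <- resolve_coeffs(coeffs, fs)
  check_freqs(freqs_hz, cf$fs)
  vals <- pdc_cpp(tensor_to_slabs(cf$A), freqs_hz / cf$fs)
  structure(list(values = vals, freqs_hz = freqs_hz, fs = cf$fs,
                 normalized = TRUE),
            class = "pdc_tensor")
}

#' Theoretical squared PDC of the ground-truth coefficients
#'
#' Applies the same PDC code path as the estimation side to the exact
#' time-varying coefficients, giving the reference against which estimates
#' are scored.
#'
#' @param params a `tvmvar_params` (e.g. from [assemble_coefficients()])
#' @param freqs_hz frequency grid in Hz
#' @return a `pdc_tensor`
#' @export
theoretical_pdc <- function(params, freqs_hz = 1:40) {
  stopifnot(inherits(params, "tvmvar_params"))
  pdc_from_coeffs(params, freqs_hz)
}

#' Time-varying PDC of multi-trial series under a trial-handling strategy
#'
#' * `CKF-1`: fit the classical Kalman filter per trial, average the MVAR
#'   coefficient trajectories across trials, then compute PDC.
#' * `CKF-2`: fit per trial, compute squared PDC per trial, average the PDC
#'   values across trials. No re-normalization is applied (none is needed:
#'   column sums are linear in the values, so the average of per-trial
#'   normalized tensors still sums to 1 over receivers — but it is not the
#'   PDC of any single averaged model).
#' * `GLKF`: fit the general linear Kalman filter on all trials jointly and
#'   compute PDC of the single trajectory.
#'
#' @param trials trials x m x N array or `trial_tensor`
#' @param strategy `"CKF-1"`, `"CKF-2"` or `"GLKF"`
#' @param config a [kalman_config()]
#' @param freqs_hz frequency grid in Hz (default 1-40 Hz)
#' @param fs sampling frequency in Hz
#' @return a `pdc_tensor`
#' @export
strategy_pdc <- function(trials, strategy = c("CKF-1", "CKF-2", "GLKF"),
                         config = kalman_config(), freqs_hz = 1:40,
                         fs = NULL) {
  strategy <- match.arg(strategy)
  if (inherits(trials, "trial_tensor")) {
    if (is.null(fs)) fs <- trials$fs
    trials <- trials$data
  }
  if (is.null(fs)) stop("fs must be supplied")
  stopifnot(length(dim(trials)) == 3)
  r <- dim(trials)[1]
  if (strategy == "GLKF") {
    traj <- glkf_fit(trials, config, fs = fs)
    return(pdc_from_coeffs(traj, freqs_hz))
  }
  fits <- lapply(seq_len(r), function(t) {
    y <- trials[t, , ]
    dim(y) <- dim(trials)[2:3]
    ckf_fit(y, config, fs = fs)
  })
  if (strategy == "CKF-1") {
    return(pdc_from_coeffs(aggregate_ckf(fits), freqs_hz))
  }
  acc <- NULL
  for (f in fits) {
    pv <- pdc_from_coeffs(f, freqs_hz)$values
    acc <- if (is.null(acc)) pv else acc + pv
  }
  structure(list(values = acc / r, freqs_hz = freqs_hz, fs = fs,
                 normalized = TRUE, trial_averaged = (r > 1)),
            class = "pdc_tensor")
}

resolve_coeffs <- function(coeffs, fs) {
  if (inherits(coeffs, "mvar_traj")) {
    list(A = coeffs$coeffs, fs = if (is.null(fs)) coeffs$fs else fs)
  } else if (inherits(coeffs, "tvmvar_params")) {
    list(A = coeffs$A, fs = if (is.null(fs)) coeffs$fs else fs)
  } else {
    if (is.null(fs)) stop("fs must be supplied for a bare coefficient tensor")
    stopifnot(length(dim(coeffs)) == 4)
    list(A = coeffs, fs = fs)
  }
}

check_freqs <- function(freqs_hz, fs) {
  if (is.null(fs)) stop("sampling frequency unknown")
  if (any(freqs_hz <= 0) || any(freqs_hz > fs / 2)) {
    stop("frequencies must lie in (0, fs/2]")
  }
  invisible(TRUE)
}

#' @export
print.pdc_tensor <- function(x, ...) {
  d <- dim(x$values)
  cat("pdc_tensor:", d[1], "x", d[2], "channels,", d[3], "frequencies,",
      d[4], "time bins",
      if (isTRUE(x$trial_averaged)) "(trial-averaged values)", "\n")
  invisible(x)
}
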