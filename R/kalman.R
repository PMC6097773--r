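#' Configuration of the Kalman-filter MVAR trackers
#'
#' @param p model order (lags), default 8
#' @param uc update constant in (0, 1) governing adaptation speed: it scales
#'   the random-walk state noise and the smoothing of the residual
#'   covariance; default 0.02
#' @param p0 initial state covariance scale (identity times `p0`)
#' @return object of class `kalman_config`
#' @export
kalman_config <- function(p = 8, uc = 0.02, p0 = 1) {
  stopifnot(p >= 1, uc > 0, uc < 1, p0 > 0)
  structure(list(p = as.integer(p), uc = uc, p0 = p0),
            class = "kalman_config")
}

# (mp x m x N) state trajectory -> (m, m, p, N) coefficient tensor
# state column i = receiver i; state row (k-1)*m + j = A_k[i, j]
stacked_to_tensor <- function(X, m, p) {
  N <- dim(X)[3]
  dim(X) <- c(m, p, m, N)        # (j, k, i, n)
  aperm(X, c(3, 1, 2, 4))        # (i, j, k, n)
}

# (m, m, p, N) tensor -> (m, m*p, N) slices [A_1 ... A_p] for the C++ core
tensor_to_slabs <- function(A) {
  d <- dim(A)
  dim(A) <- c(d[1], d[2] * d[3], d[4])
  A
}

as_series_matrix <- function(series) {
  if (inherits(series, "trial_tensor")) {
    stopifnot(dim(series$data)[1] == 1)
    out <- series$data[1, , ]
    dim(out) <- dim(series$data)[2:3]
    return(out)
  }
  as.matrix(series)
}

#' Track time-varying MVAR coefficients with the classical Kalman filter
#'
#' Single-trial random-walk state-space tracker: the MVAR coefficient matrix
#' follows a random walk whose innovation covariance is `uc * tr(P)/dim * I`
#' (relative adaptation), the measurement equation regresses each sample on
#' the `p` past samples, and the measurement-noise level is the trace of an
#' exponentially smoothed residual covariance (smoothing constant `uc`).
#' The input is divided by its global RMS before filtering — MVAR
#' coefficients are invariant under global rescaling, and this keeps the
#' filter initialization scale-free. Estimates for the first `p` bins are
#' back-filled with the first valid estimate.
#'
#' @param series m x N numeric matrix (or single-trial `trial_tensor`)
#' @param config a [kalman_config()]
#' @param fs sampling frequency stored with the result (Hz)
#' @return object of class `mvar_traj`: list with `coeffs`
#'   (m x m x p x N tensor of `A_k(n)` estimates), `resid` (m x m x N
#'   residual covariance trajectory, on the normalized scale), `p`, `uc`,
#'   `fs`, `method`
#' @export
ckf_fit <- function(series, config = kalman_config(), fs = NULL) {
  y <- as_series_matrix(series)
  m <- nrow(y); N <- ncol(y)
  stopifnot(m >= 2, N > config$p)
  scl <- sqrt(mean(y^2))
  if (scl == 0) scl <- 1
  res <- ckf_cpp(y / scl, config$p, config$uc, config$p0)
  structure(list(coeffs = stacked_to_tensor(res$coeffs, m, config$p),
                 resid = res$resid, p = config$p, uc = config$uc,
                 fs = if (is.null(fs) && inherits(series, "trial_tensor"))
                   series$fs else fs,
                 method = "CKF"),
            class = "mvar_traj")
}

#' Track time-varying MVAR coefficients with the general linear Kalman filter
#'
#' Multi-trial formulation: at each time bin the measurements of all trials
#' are stacked into one observation block sharing a single coefficient
#' state, so one trajectory is estimated from all trials jointly. State
#' adaptation matches [ckf_fit()]; the measurement-noise covariance is an
#' exponentially smoothed across-trial innovation outer product (an r x r
#' matrix), so the single-trial special case is regularized differently
#' from the classical filter and the two trackers are distinct estimators.
#'
#' @param trials trials x m x N array (or a `trial_tensor`)
#' @param config a [kalman_config()]
#' @param fs sampling frequency stored with the result (Hz)
#' @return an `mvar_traj` (see [ckf_fit()]), `method = "GLKF"`
#' @export
glkf_fit <- function(trials, config = kalman_config(), fs = NULL) {
  if (inherits(trials, "trial_tensor")) {
    if (is.null(fs)) fs <- trials$fs
    trials <- trials$data
  }
  stopifnot(length(dim(trials)) == 3)
  r <- dim(trials)[1]; m <- dim(trials)[2]; N <- dim(trials)[3]
  stopifnot(r >= 1, m >= 2, N > config$p)
  scl <- sqrt(mean(trials^2))
  if (scl == 0) scl <- 1
  y <- aperm(trials / scl, c(2, 3, 1))    # (m, N, r) cube for the C++ core
  res <- glkf_cpp(y, config$p, config$uc, config$p0)
  structure(list(coeffs = stacked_to_tensor(res$coeffs, m, config$p),
                 resid = res$resid, p = config$p, uc = config$uc,
                 fs = fs, method = "GLKF"),
            class = "mvar_traj")
}

#' Average single-trial MVAR trajectories
#'
#' Element-wise mean of the coefficient (and residual-covariance)
#' trajectories across trials; the aggregation used by the CKF-1 strategy.
#'
#' @param trajectories list of `mvar_traj` objects with identical shape
#' @return an `mvar_traj`
#' @export
aggregate_ckf <- function(trajectories) {
  stopifnot(length(trajectories) >= 1)
  d1 <- dim(trajectories[[1]]$coeffs)
  for (tr in trajectories) {
    if (!identical(dim(tr$coeffs), d1)) stop("trajectory shape mismatch")
  }
  out <- trajectories[[1]]
  out$coeffs <- Reduce(`+`, lapply(trajectories, `[[`, "coeffs")) /
    length(trajectories)
  out$resid <- Reduce(`+`, lapply(trajectories, `[[`, "resid")) /
    length(trajectories)
  out$method <- "CKF-averaged"
  out
}

#' @export
print.mvar_traj <- function(x, ...) {
  d <- dim(x$coeffs)
  cat("mvar_traj (", x$method, "): ", d[1], " channels, order ", d[3],
      ", ", d[4], " time bins, UC = ", x$uc, "\n", sep = "")
  invisible(x)
}
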