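#' Construct a multi-trial time-series container
#'
#' @param data numeric array (trials x channels x samples)
#' @param fs sampling frequency in Hz
#' @param t0_ms time of sample 1 in ms relative to stimulus onset
#' @param channels character vector of channel labels
#' @return object of class `trial_tensor`
#' @export
trial_tensor <- function(data, fs, t0_ms, channels = NULL) {
  stopifnot(length(dim(data)) == 3)
  if (is.null(channels)) channels <- paste0("ch", seq_len(dim(data)[2]))
  stopifnot(length(channels) == dim(data)[2])
  structure(list(data = data, fs = fs, t0_ms = t0_ms, channels = channels),
            class = "trial_tensor")
}

#' @export
print.trial_tensor <- function(x, ...) {
  d <- dim(x$data)
  cat("trial_tensor:", d[1], "trials x", d[2], "channels x", d[3],
      "samples @", x$fs, "Hz (t0 =", x$t0_ms, "ms)\n")
  invisible(x)
}

#' Simulate multi-trial source signals from the ground-truth model
#'
#' Each trial is generated iteratively in time from the time-varying MVAR
#' recursion: the V1 channel carries an independent realization of the
#' AR(10) visual-input process, every other channel receives its lagged
#' network input plus a white Gaussian innovation whose amplitude is rescaled
#' at every time point so that the signal-to-innovation power ratio equals
#' `model$source_snr` (innovation s.d. = |deterministic part| / sqrt(SNR)).
#'
#' @param model a `gt_model`
#' @param n_trials number of trials
#' @param seed optional integer seed
#' @param keep_components if `TRUE`, the noise-free deterministic part and
#'   the innovations are returned alongside the data
#' @return list with `trials` (a `trial_tensor`), `params` (the exact
#'   `tvmvar_params` used) and, if requested, `signal` and `innovations`
#'   arrays of the same shape as the data. For the V1 input channel the
#'   "signal" is the injected input realization and the innovation is zero.
#' @export
simulate_trials <- function(model, n_trials, seed = NULL,
                            keep_components = FALSE) {
  stopifnot(inherits(model, "gt_model"), n_trials >= 1)
  if (!is.null(seed)) set.seed(seed)
  params <- assemble_coefficients(model)
  m <- dim(params$A)[1]; p <- dim(params$A)[3]; N <- dim(params$A)[4]
  v1 <- match(model$input_region, model$regions$name)
  snr <- model$source_snr

  # stacked coefficient matrices [A_1 ... A_p] per time bin, built once
  Astack <- vector("list", N)
  for (n in seq_len(N)) {
    An <- params$A[, , , n]
    dim(An) <- c(m, m * p)
    Astack[[n]] <- An
  }

  data <- array(0, dim = c(n_trials, m, N))
  if (keep_components) {
    sig <- array(0, dim = c(n_trials, m, N))
    innov <- array(0, dim = c(n_trials, m, N))
  }
  not_v1 <- setdiff(seq_len(m), v1)
  for (r in seq_len(n_trials)) {
    input <- generate_input_signal(N)
    y <- matrix(0, m, N)
    past <- numeric(m * p)
    for (n in seq_len(N)) {
      # past vector = c(y[, n-1], ..., y[, n-p]), zeros before the start
      for (k in seq_len(p)) {
        past[(k - 1) * m + seq_len(m)] <- if (n - k >= 1) y[, n - k] else 0
      }
      s <- as.numeric(Astack[[n]] %*% past)
      s[v1] <- input[n]
      sd_n <- abs(s) / sqrt(snr)
      sd_n[v1] <- 0
      eps <- rnorm(m) * sd_n
      y[, n] <- s + eps
      if (!all(is.finite(y[, n])) || max(abs(y[, n])) > 1e9) {
        stop("simulation diverged at time bin ", n)
      }
      if (keep_components) {
        sig[r, , n] <- s
        innov[r, , n] <- eps
      }
    }
    data[r, , ] <- y
  }
  out <- list(
    trials = trial_tensor(data, fs = model$fs, t0_ms = -model$baseline_ms,
                          channels = model$regions$name),
    params = params
  )
  if (keep_components) {
    out$signal <- sig
    out$innovations <- innov
    out$input_channel <- v1
  }
  out
}

#' Empirical source-level signal-to-innovation power ratio
#'
#' Given the components stored by [simulate_trials()], computes at each time
#' point the across-trial (and non-input channel) ratio of noise-free signal
#' power to realized innovation power, skipping time points where no
#' innovation power has accumulated yet.
#'
#' @param sim result of `simulate_trials(..., keep_components = TRUE)`
#' @return list with per-time-point `ratio` and its time average `mean_ratio`
#' @export
source_snr_profile <- function(sim) {
  stopifnot(!is.null(sim$signal))
  ch <- setdiff(seq_len(dim(sim$signal)[2]), sim$input_channel)
  s2 <- apply(sim$signal[, ch, , drop = FALSE]^2, 3, sum)
  e2 <- apply(sim$innovations[, ch, , drop = FALSE]^2, 3, sum)
  ok <- e2 > 0
  ratio <- ifelse(ok, s2 / e2, NA_real_)
  list(ratio = ratio, mean_ratio = mean(ratio[ok]))
}
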