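#' Build the default visual spatial attention ground-truth model
#'
#' Loads the packaged fixture describing a 10-region directed network of the
#' visual spatial attention system: a V1 input node, bilateral visual areas
#' (VA), intraparietal sulci (IPS), frontal eye fields (FEF), and right
#' temporoparietal junction (TPJ), ventral frontal cortex / anterior insula
#' (VFC/AI) and middle frontal gyrus (MFG). Interhemispheric VA/IPS/FEF pairs
#' are coupled bidirectionally with a stationary strength of 0.5; all other
#' connections carry a stationary baseline of 0.2 plus a raised-cosine
#' time-varying bump. Stimulus-driven couplings ramp up from 100 ms after
#' stimulus onset, top-down couplings from 300 ms (feedback returns of
#' reciprocal pairs from 500 ms so that the network stays stable at every
#' time bin). Visual-input couplings act at a 4 ms lag (1 sample at 256 Hz),
#' all others at 16 ms (4 samples).
#'
#' @param config optional named list of overrides. Entries of `params`
#'   (e.g. `fs`, `duration_ms`, `source_snr`, `tv_peak_amplitude`) replace the
#'   fixture defaults; a `connections` data frame (same columns as
#'   `model$connections`) replaces the connection schedule.
#' @return an object of class `gt_model`: list with `regions` (data frame of
#'   name, label, MNI coordinates, hemisphere), `connections` (data frame with
#'   sender, receiver, lag_ms, lag (samples), category, baseline strength and
#'   bump parameters), sampling fields `fs`, `duration_ms`, `baseline_ms`,
#'   `source_snr`, the maximal lag `p_true`, and sample counts `n_samples`,
#'   `n_baseline`.
#' @examples
#' model <- build_attention_model()
#' nrow(model$connections)   # 23 directed connections
#' @export
build_attention_model <- function(config = NULL) {
  fx <- attention_fixture()
  params <- fx$params
  if (!is.null(config)) {
    bad <- setdiff(names(config), c(names(params), "connections"))
    if (length(bad) > 0) {
      stop("unknown override(s): ", paste(bad, collapse = ", "))
    }
    params <- modifyList(params, config[setdiff(names(config), "connections")])
  }

  regions <- do.call(rbind, lapply(fx$regions, function(r) {
    xyz <- unlist(r$mni_xyz)
    data.frame(name = r$name, label = r$label,
               x = xyz[1], y = xyz[2], z = xyz[3],
               hemisphere = r$hemisphere, stringsAsFactors = FALSE)
  }))
  if (anyDuplicated(regions$name)) stop("region names must be unique")

  if (!is.null(config$connections)) {
    connections <- config$connections
  } else {
    connections <- do.call(rbind, lapply(fx$connections, function(cn) {
      tv <- cn$tv
      data.frame(sender = cn$sender, receiver = cn$receiver,
                 lag_ms = cn$lag_ms, category = cn$category,
                 baseline_strength = if (cn$category == "interhemispheric")
                   params$interhemispheric_strength else params$baseline_strength,
                 tv_onset_ms = if (is.null(tv)) NA_real_ else tv$onset_ms,
                 tv_duration_ms = if (is.null(tv)) NA_real_ else tv$duration_ms,
                 tv_peak = if (is.null(tv)) NA_real_ else params$tv_peak_amplitude,
                 stringsAsFactors = FALSE)
    }))
  }

  unknown <- setdiff(unique(c(connections$sender, connections$receiver)),
                     regions$name)
  if (length(unknown) > 0) {
    stop("connection references unknown region(s): ",
         paste(unknown, collapse = ", "))
  }
  if (any(connections$sender == connections$receiver)) {
    stop("self-connections are not allowed")
  }

  # nominal ms lags are converted to the nearest integer sample lag
  lag_samples <- round(connections$lag_ms * params$fs / 1000)
  if (any(lag_samples < 1)) {
    stop("connection lags must convert to sample lags >= 1 at fs = ",
         params$fs, " Hz")
  }
  connections$lag <- as.integer(lag_samples)

  model <- structure(list(
    regions = regions,
    connections = connections,
    fs = params$fs,
    duration_ms = params$duration_ms,
    baseline_ms = params$baseline_ms,
    source_snr = params$source_snr,
    p_true = max(c(connections$lag, 1L)),
    n_samples = as.integer(round(params$duration_ms * params$fs / 1000)),
    n_baseline = as.integer(round(params$baseline_ms * params$fs / 1000)),
    input_region = "V1"
  ), class = "gt_model")

  params_tv <- assemble_coefficients(model)
  rho <- max(companion_spectral_radius(params_tv))
  if (rho >= 1) {
    stop("assembled time-varying MVAR model is unstable ",
         "(max companion spectral radius ", signif(rho, 4), " >= 1)")
  }
  model
}

attention_fixture <- function() {
  path <- system.file("extdata", "attention_model.json", package = "tvconnsim",
                      mustWork = TRUE)
  jsonlite::read_json(path, simplifyVector = FALSE)
}

input_ar_coefficients <- function() {
  fx <- attention_fixture()
  unlist(fx$input_ar$phi)
}

mni_affine <- function() {
  fx <- attention_fixture()
  list(center = unlist(fx$mni_affine$center), scale = fx$mni_affine$scale)
}

#' Time axis of a ground-truth model
#'
#' @param model a `gt_model`
#' @return time of each sample in ms relative to stimulus onset (the end of
#'   the baseline window); sample 1 is at `-baseline_ms`.
#' @export
model_time_ms <- function(model) {
  (seq_len(model$n_samples) - 1) / model$fs * 1000 - model$baseline_ms
}

raised_cosine <- function(t_ms, onset_ms, duration_ms, peak) {
  inside <- t_ms >= onset_ms & t_ms <= onset_ms + duration_ms
  out <- numeric(length(t_ms))
  out[inside] <- peak * 0.5 * (1 - cos(2 * pi * (t_ms[inside] - onset_ms) / duration_ms))
  out
}

#' Assemble the time-varying MVAR coefficient tensor of a model
#'
#' Expands the connection schedule into the coefficient tensor
#' `A[i, j, k, n]`: influence of sender `j` on receiver `i` at lag `k`
#' (samples) and time bin `n`.
#'
#' @param model a `gt_model`
#' @param p model order of the returned tensor; defaults to the largest lag
#'   in the schedule. Larger values zero-pad the extra lags.
#' @param include_input_ar if `TRUE`, the autoregressive self-coefficients of
#'   the V1 input process are written onto the input channel's diagonal
#'   (lags up to `p`). The simulated V1 channel is an AR(10) process, so the
#'   full generating process carries these coefficients; they only matter
#'   for the column normalization of theoretical PDC (the diagonal itself is
#'   excluded from every figure of merit), but omitting them would score
#'   estimators against a reference that pretends the input channel is white.
#' @return object of class `tvmvar_params`: list with `A` (m x m x p x N),
#'   `p`, `fs`, `regions` (channel names) and `t_ms`.
#' @export
assemble_coefficients <- function(model, p = model$p_true,
                                  include_input_ar = FALSE) {
  stopifnot(inherits(model, "gt_model"), p >= model$p_true)
  m <- nrow(model$regions)
  N <- model$n_samples
  t_ms <- model_time_ms(model)
  A <- array(0, dim = c(m, m, p, N))
  if (include_input_ar) {
    phi <- input_ar_coefficients()
    v1 <- match(model$input_region, model$regions$name)
    for (k in seq_len(min(p, length(phi)))) A[v1, v1, k, ] <- phi[k]
  }
  for (r in seq_len(nrow(model$connections))) {
    cn <- model$connections[r, ]
    i <- match(cn$receiver, model$regions$name)
    j <- match(cn$sender, model$regions$name)
    strength <- rep(cn$baseline_strength, N)
    if (!is.na(cn$tv_onset_ms)) {
      strength <- strength +
        raised_cosine(t_ms, cn$tv_onset_ms, cn$tv_duration_ms, cn$tv_peak)
    }
    A[i, j, cn$lag, ] <- A[i, j, cn$lag, ] + strength
  }
  structure(list(A = A, p = p, fs = model$fs,
                 regions = model$regions$name, t_ms = t_ms),
            class = "tvmvar_params")
}

#' Companion-form spectral radius at every time bin
#'
#' Treats the coefficients at each time bin as a frozen stationary MVAR model
#' and returns the spectral radius of its companion matrix; values below 1
#' indicate pointwise stability.
#'
#' @param params a `tvmvar_params`
#' @return numeric vector, one spectral radius per time bin
#' @export
companion_spectral_radius <- function(params) {
  A <- params$A
  m <- dim(A)[1]; p <- dim(A)[3]; N <- dim(A)[4]
  idx <- which(apply(A != 0, 4, any))
  if (length(idx) == 0) return(numeric(N))
  rho <- numeric(N)
  comp <- matrix(0, m * p, m * p)
  if (p > 1) comp[(m + 1):(m * p), 1:(m * (p - 1))] <- diag(m * (p - 1))
  prev <- NULL
  for (n in seq_len(N)) {
    An <- A[, , , n, drop = FALSE]
    dim(An) <- c(m, m * p)
    if (!is.null(prev) && identical(An, prev$An)) {
      rho[n] <- prev$rho
      next
    }
    comp[1:m, ] <- An
    r <- max(Mod(eigen(comp, only.values = TRUE)$values))
    rho[n] <- r
    prev <- list(An = An, rho = r)
  }
  rho
}

#' @export
print.gt_model <- function(x, ...) {
  cat("Ground-truth time-varying MVAR model\n")
  cat("  regions:    ", nrow(x$regions), "\n")
  cat("  connections:", nrow(x$connections), "directed (of",
      nrow(x$regions) * (nrow(x$regions) - 1), "possible)\n")
  cat("  fs:         ", x$fs, "Hz;", x$n_samples, "samples (",
      x$n_baseline, "baseline )\n")
  cat("  source SNR: ", x$source_snr, "\n")
  invisible(x)
}
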