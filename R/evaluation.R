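#' Existing / non-existing connection masks of a model
#'
#' @param model a `gt_model`
#' @return list with logical m x m matrices `existing` (ordered pairs with a
#'   nonzero ground-truth coupling) and `nonexisting` (all remaining
#'   off-diagonal ordered pairs); `[i, j]` refers to the connection from
#'   sender `j` to receiver `i`
#' @export
connection_masks <- function(model) {
  m <- nrow(model$regions)
  ex <- matrix(FALSE, m, m,
               dimnames = list(model$regions$name, model$regions$name))
  for (r in seq_len(nrow(model$connections))) {
    i <- match(model$connections$receiver[r], model$regions$name)
    j <- match(model$connections$sender[r], model$regions$name)
    ex[i, j] <- TRUE
  }
  non <- !ex
  diag(non) <- FALSE
  list(existing = ex, nonexisting = non)
}

#' Mean squared error between estimated and theoretical MVAR trajectories
#'
#' Mean over time bins, lags and the masked (receiver, sender) entries of
#' the squared coefficient differences. The theoretical tensor is zero-padded
#' to the estimated model order if needed.
#'
#' @param estimated an `mvar_traj` (or m x m x p x N tensor)
#' @param theoretical a `tvmvar_params` (or tensor of the same channel/time
#'   grid)
#' @param mask logical m x m matrix of entries to include (diagonal allowed)
#' @return scalar MSE
#' @export
mse_mvar <- function(estimated, theoretical, mask) {
  Ae <- if (inherits(estimated, "mvar_traj")) estimated$coeffs else estimated
  At <- if (inherits(theoretical, "tvmvar_params")) theoretical$A
        else theoretical
  de <- dim(Ae); dt <- dim(At)
  if (!identical(de[c(1, 2, 4)], dt[c(1, 2, 4)])) {
    stop("estimated/theoretical grids differ (channels or time bins)")
  }
  if (dt[3] < de[3]) {
    pad <- array(0, dim = c(dt[1], dt[2], de[3] - dt[3], dt[4]))
    At <- abind4(At, pad)
  } else if (dt[3] > de[3]) {
    stop("estimated model order smaller than theoretical order")
  }
  stopifnot(identical(dim(mask), de[1:2]))
  if (!any(mask)) stop("empty mask")
  d2 <- (Ae - At)^2
  dim(d2) <- c(de[1] * de[2], de[3] * de[4])
  mean(d2[as.vector(mask), , drop = FALSE])
}

abind4 <- function(a, b) {
  da <- dim(a); db <- dim(b)
  out <- array(0, dim = c(da[1], da[2], da[3] + db[3], da[4]))
  out[, , seq_len(da[3]), ] <- a
  out[, , da[3] + seq_len(db[3]), ] <- b
  out
}

#' Mean squared error between estimated and theoretical squared PDC
#'
#' Mean over frequencies, time bins and the masked off-diagonal
#' (receiver, sender) pairs of squared differences of squared PDC values.
#' Diagonal entries are always excluded: column normalization makes them
#' complements of the outflow and they carry no directed information.
#'
#' @param estimated a `pdc_tensor` (or values array)
#' @param theoretical a `pdc_tensor` on the same (frequency, time) grid
#' @param mask logical m x m matrix of pairs to include
#' @return scalar MSE
#' @export
mse_pdc <- function(estimated, theoretical, mask) {
  Pe <- if (inherits(estimated, "pdc_tensor")) estimated$values else estimated
  Pt <- if (inherits(theoretical, "pdc_tensor")) theoretical$values
        else theoretical
  if (!identical(dim(Pe), dim(Pt))) stop("PDC grids differ")
  d <- dim(Pe)
  stopifnot(identical(dim(mask), d[1:2]))
  mask <- mask & !diag(TRUE, d[1])
  if (!any(mask)) stop("mask empty after excluding the diagonal")
  d2 <- (Pe - Pt)^2
  dim(d2) <- c(d[1] * d[2], d[3] * d[4])
  mean(d2[as.vector(mask), , drop = FALSE])
}

#' Run the SNR-by-trial-count factorial benchmark
#'
#' Full pipeline per cell: the ground-truth source trials are simulated
#' once; each noise realization then redraws the scalp sensor noise,
#' re-estimates the noise covariance and sLORETA kernel, reconstructs the
#' ROI member time series, selects dipoles under each selection strategy,
#' tracks MVAR coefficients under each Kalman strategy for each trial
#' count, computes squared PDC, and scores both figures of merit against
#' the theoretical references separately for existing and non-existing
#' connections.
#'
#' @param snr_levels scalp SNR levels (power ratios)
#' @param trial_counts trial counts (subsets of the simulated trials)
#' @param n_realizations scalp-noise realizations per SNR level
#' @param selection subset of `c("GT1","GT2","DD1","DD2","DD3","DD4","DD5")`
#' @param kalman subset of `c("CKF-1","CKF-2","GLKF")`
#' @param seed master seed; realization seeds are derived as
#'   `(seed + 7919 * counter) mod (2^31 - 1)` with a documented counter per
#'   (SNR index, realization)
#' @param model a `gt_model`
#' @param config a [kalman_config()]
#' @param freqs_hz PDC frequency grid
#' @param n_vertices,n_electrodes,fold_amplitude,roi_size head-model and ROI
#'   geometry settings (desk-scale defaults)
#' @param progress print per-dataset progress
#' @return data frame of class `study_result` with one row per (kalman
#'   strategy, selection, SNR, trial count, realization, connection class)
#'   and columns `mse_mvar`, `mse_pdc`
#' @export
run_factorial_study <- function(snr_levels = c(1, 3, 5, 10),
                                trial_counts = c(3, 5, 10, 20, 40, 60, 80, 100),
                                n_realizations = 100,
                                selection = c("GT2", "DD1", "DD2", "DD3"),
                                kalman = c("CKF-1", "CKF-2", "GLKF"),
                                seed = 1,
                                model = build_attention_model(),
                                config = kalman_config(),
                                freqs_hz = 1:40,
                                n_vertices = 2000, n_electrodes = 64,
                                fold_amplitude = 9, roi_size = 45,
                                progress = FALSE) {
  kalman <- match.arg(kalman, c("CKF-1", "CKF-2", "GLKF"), several.ok = TRUE)
  trial_counts <- sort(unique(trial_counts))
  n_max <- max(trial_counts)

  sim <- simulate_trials(model, n_max, seed = seed)
  hm <- build_head_model(n_vertices, n_electrodes,
                         fold_amplitude = fold_amplitude)
  lf <- compute_leadfield(hm$head, hm$sources, hm$sensors)
  gt_idx <- map_ground_truth_dipoles(hm$sources, model)
  graph <- mesh_graph(hm$sources)
  rois <- define_rois(hm$sources, gt_idx, roi_size, graph = graph)
  signs <- lapply(rois, function(roi) dominant_sign_flip(hm$sources, roi))
  member_rows <- sort(unique(unlist(lapply(rois, `[[`, "members"))))
  roi_local <- lapply(rois, function(roi) match(roi$members, member_rows))

  # scoring references describe the full generating process, including the
  # AR self-dynamics of the V1 input channel (diagonal entries are excluded
  # from every mask; they only fix the PDC column normalization of sender V1)
  theo_params <- assemble_coefficients(model, p = config$p,
                                       include_input_ar = TRUE)
  p_full <- max(config$p, length(input_ar_coefficients()))
  theo_pdc <- theoretical_pdc(
    assemble_coefficients(model, p = p_full, include_input_ar = TRUE),
    freqs_hz)
  masks <- connection_masks(model)
  gt_mean <- apply(sim$trials$data, c(2, 3), mean)   # regions x samples
  m <- nrow(gt_mean)
  # state-layout theoretical trajectory and integer masks for the fast path
  theo_state <- aperm(theo_params$A, c(2, 3, 1, 4))
  dim(theo_state) <- c(m * config$p, m, dim(theo_params$A)[4])
  imasks <- lapply(masks, function(x) { storage.mode(x) <- "integer"; x })
  need_resolution <- any(selection %in% c("DD4", "DD5"))

  rows <- list()
  for (si in seq_along(snr_levels)) {
    snr <- snr_levels[si]
    for (rep_i in seq_len(n_realizations)) {
      counter <- (si - 1) * max(n_realizations, 1000) + rep_i
      seed_r <- (seed + 7919 * counter) %% 2147483647
      scalp <- project_and_add_noise(lf, sim$trials, snr,
                                     vertex_idx = gt_idx, seed = seed_r)
      ncov <- estimate_noise_covariance(scalp$trials)
      kern <- compute_sloreta_kernel(lf, ncov, snr)
      est <- apply_kernel(kern, scalp$trials, rows = member_rows)
      aux <- list()
      if (need_resolution) aux$resolution <- resolution_matrix(kern, lf)

      for (sel in selection) {
        Y <- array(0, dim = c(n_max, m, dim(gt_mean)[2]))
        for (g in seq_len(m)) {
          roi <- rois[[g]]
          sub <- trial_tensor(
            est$data[, roi_local[[g]], , drop = FALSE],
            fs = est$fs, t0_ms = est$t0_ms)
          aux$gt_series <- gt_mean[g, ]
          res <- select_dipole(sel, roi, sub, signs = signs[[g]], aux = aux)
          Y[, g, ] <- res$series
        }
        cell_rows <- score_strategies(Y, trial_counts, kalman, config,
                                      freqs_hz, theo_state, theo_pdc$values,
                                      imasks, fs = model$fs)
        for (cr in cell_rows) {
          cr$selection <- sel; cr$snr <- snr; cr$realization <- rep_i
          rows[[length(rows) + 1]] <- cr
        }
      }
      if (progress) {
        message("SNR ", snr, " realization ", rep_i, " done")
      }
    }
  }
  out <- do.call(rbind, lapply(rows, as.data.frame))
  out <- out[, c("strategy", "selection", "snr", "n_trials", "realization",
                 "class", "mse_mvar", "mse_pdc")]
  class(out) <- c("study_result", class(out))
  out
}

# fit all Kalman strategies on nested trial subsets and score both figures
# of merit. Works in the compiled state layout throughout (coefficient
# trajectories as mp x m x N cubes, theoretical reference pre-converted)
# to avoid per-trial layout conversions; returns a list of row lists.
score_strategies <- function(Y, trial_counts, kalman, config, freqs_hz,
                             theo_state, theo_pdc_values, imasks, fs) {
  n_max <- dim(Y)[1]
  fn <- freqs_hz / fs
  classes <- c("existing", "nonexisting")
  rows <- list()
  rms <- function(x) { s <- sqrt(mean(x^2)); if (s == 0) 1 else s }

  if (any(c("CKF-1", "CKF-2") %in% kalman)) {
    coeff_sum <- NULL
    pdc_sum <- NULL
    mvar_trial_sum <- c(existing = 0, nonexisting = 0)
    checkpoints <- sort(trial_counts)
    ci <- 1
    for (t in seq_len(n_max)) {
      y <- Y[t, , ]
      dim(y) <- dim(Y)[2:3]
      fit <- ckf_cpp(y / rms(y), config$p, config$uc, config$p0)$coeffs
      coeff_sum <- if (is.null(coeff_sum)) fit else coeff_sum + fit
      if ("CKF-2" %in% kalman) {
        pv <- pdc_state_cpp(fit, fn)
        pdc_sum <- if (is.null(pdc_sum)) pv else pdc_sum + pv
        for (cls in classes) {
          mvar_trial_sum[cls] <- mvar_trial_sum[cls] +
            masked_mse_state_cpp(fit, theo_state, imasks[[cls]])
        }
      }
      while (ci <= length(checkpoints) && t == checkpoints[ci]) {
        nt <- checkpoints[ci]
        if ("CKF-1" %in% kalman) {
          avg <- coeff_sum / nt
          pdc1 <- pdc_state_cpp(avg, fn)
          for (cls in classes) {
            rows[[length(rows) + 1]] <- list(
              strategy = "CKF-1", n_trials = nt, class = cls,
              mse_mvar = masked_mse_state_cpp(avg, theo_state, imasks[[cls]]),
              mse_pdc = masked_mse_pdc_cpp(pdc1, theo_pdc_values,
                                           imasks[[cls]]))
          }
        }
        if ("CKF-2" %in% kalman) {
          pdc2 <- pdc_sum / nt
          for (cls in classes) {
            rows[[length(rows) + 1]] <- list(
              strategy = "CKF-2", n_trials = nt, class = cls,
              mse_mvar = unname(mvar_trial_sum[cls]) / nt,
              mse_pdc = masked_mse_pdc_cpp(pdc2, theo_pdc_values,
                                           imasks[[cls]]))
          }
        }
        ci <- ci + 1
      }
    }
  }
  if ("GLKF" %in% kalman) {
    for (nt in trial_counts) {
      ysub <- Y[seq_len(nt), , , drop = FALSE]
      ycube <- aperm(ysub / rms(ysub), c(2, 3, 1))
      traj <- glkf_cpp(ycube, config$p, config$uc, config$p0)$coeffs
      pdcg <- pdc_state_cpp(traj, fn)
      for (cls in classes) {
        rows[[length(rows) + 1]] <- list(
          strategy = "GLKF", n_trials = nt, class = cls,
          mse_mvar = masked_mse_state_cpp(traj, theo_state, imasks[[cls]]),
          mse_pdc = masked_mse_pdc_cpp(pdcg, theo_pdc_values, imasks[[cls]]))
      }
    }
  }
  rows
}

#' Median figures of merit of a factorial study
#'
#' @param study a `study_result`
#' @param by grouping columns (default strategy and connection class)
#' @return data frame of medians of both figures of merit per group
#' @export
study_medians <- function(study, by = c("strategy", "class")) {
  agg <- stats::aggregate(study[, c("mse_mvar", "mse_pdc")],
                   by = study[by], FUN = median)
  agg[do.call(order, agg[by]), , drop = FALSE]
}
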