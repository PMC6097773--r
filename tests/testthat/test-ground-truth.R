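test_that("default attention model matches the documented network", {
  m <- default_model()
  expect_equal(nrow(m$regions), 10)
  v1 <- m$regions[m$regions$name == "V1", ]
  expect_equal(unlist(v1[, c("x", "y", "z")], use.names = FALSE),
               c(6.3, -82.3, -3.7))
  expect_equal(nrow(m$connections), 23)
  expect_equal(nrow(m$regions) * (nrow(m$regions) - 1), 90)

  inter <- m$connections[m$connections$category == "interhemispheric", ]
  expect_true(all(inter$baseline_strength == 0.5))
  expect_true(all(is.na(inter$tv_onset_ms)))
  # symmetric directed pairs
  key <- paste(inter$sender, inter$receiver)
  rev <- paste(inter$receiver, inter$sender)
  expect_setequal(key, rev)

  tv <- m$connections[!is.na(m$connections$tv_onset_ms), ]
  expect_true(all(tv$baseline_strength == 0.2))
  expect_true(all(m$connections$sender != m$connections$receiver))
  expect_equal(m$n_samples, 307)   # round(1.2 s * 256 Hz)
  expect_equal(m$n_baseline, 51)
})

test_that("assembled coefficients are pointwise stable and lag-consistent", {
  m <- default_model()
  params <- assemble_coefficients(m)
  expect_equal(dim(params$A), c(10, 10, 4, 307))
  rho <- companion_spectral_radius(params)
  expect_true(max(rho) < 1)
  # 16 ms -> 4 samples, 4 ms -> 1 sample at 256 Hz
  expect_equal(sort(unique(m$connections$lag)), c(1L, 4L))
  expect_equal(m$p_true, 4L)
})

test_that("bad overrides are rejected with a diagnostic", {
  expect_error(build_attention_model(list(nonsense = 1)), "unknown override")
  bad <- default_model()$connections
  bad$sender[1] <- "NOT_A_REGION"
  expect_error(build_attention_model(list(connections = bad)),
               "unknown region")
  # raising the bump amplitude far enough destabilizes the network
  expect_error(build_attention_model(list(tv_peak_amplitude = 2)),
               "unstable")
})

test_that("input signal generator is deterministic with the right spectrum", {
  expect_identical(generate_input_signal(512, seed = 11),
                   generate_input_signal(512, seed = 11))
  expect_equal(generate_input_signal(64, innovations = rep(0, 64)),
               rep(0, 64))

  # oracle: AR transfer function of the fixture coefficients
  phi <- tvconnsim:::input_ar_coefficients()
  expect_length(phi, 10)
  f <- seq(0.5, 40, by = 0.5)
  H2 <- vapply(f, function(ff) {
    1 / Mod(1 - sum(phi * exp(-2i * pi * ff / 256 * (1:10))))^2
  }, numeric(1))
  trend <- lm(log(H2) ~ log(f))
  expect_gte(f[which.max(resid(trend))], 8)
  expect_lte(f[which.max(resid(trend))], 12)
  # 1/f-like decay: strong negative log-log slope
  expect_lt(coef(trend)[2], -0.5)

  # realized spectrum of a long draw shows the same alpha peak
  x <- generate_input_signal(10240, seed = 21)
  sp <- spec.pgram(ts(x, frequency = 256), spans = c(25, 25), plot = FALSE,
                   taper = 0.1)
  keep <- sp$freq >= 0.5 & sp$freq <= 40
  tr2 <- lm(log(sp$spec[keep]) ~ log(sp$freq[keep]))
  fpk <- sp$freq[keep][which.max(resid(tr2))]
  expect_gte(fpk, 8)
  expect_lte(fpk, 12)
})

test_that("SBC order selection finds known orders", {
  set.seed(42)
  e <- rnorm(5500)
  y <- as.numeric(stats::filter(e, c(0.9, -0.5), method = "recursive"))[501:5500]
  expect_equal(as.integer(sbc_order_select(y, 10)), 2L)

  set.seed(43)
  expect_equal(as.integer(sbc_order_select(rnorm(3000), 10)), 1L)

  expect_error(sbc_order_select(rbind(rnorm(500), rep(1, 500)), 5),
               "channel 2")
})

test_that("trial simulation has the documented shape and determinism", {
  m <- default_model()
  sim1 <- simulate_trials(m, 3, seed = 7)
  sim2 <- simulate_trials(m, 3, seed = 7)
  expect_identical(sim1$trials$data, sim2$trials$data)
  expect_equal(dim(sim1$trials$data), c(3, 10, 307))
  expect_true(all(is.finite(sim1$trials$data)))

  # with every connection removed, only the V1 input channel is active
  empty <- default_model()$connections[0, ]
  m0 <- build_attention_model(list(connections = empty))
  sim0 <- simulate_trials(m0, 2, seed = 1)
  v1 <- match("V1", m0$regions$name)
  expect_true(all(sim0$trials$data[, -v1, ] == 0))
  expect_gt(sd(sim0$trials$data[, v1, ]), 0)
})

test_that("stationary baseline couplings are recovered by least squares", {
  m <- build_attention_model(list(tv_peak_amplitude = 0))
  # tv bumps flattened: every connection is stationary at its baseline.
  # At source SNR 20 the innovations are small, so the channels are nearly
  # deterministic mixtures of the (strongly autocorrelated) V1 input and
  # the regression is badly conditioned; many trials are needed before the
  # sampling error of individual coefficients settles, and couplings sent
  # by the near-unit-root input channel itself remain the most variable.
  set.seed(123)
  sim <- simulate_trials(m, 1000)
  A_true <- assemble_coefficients(m)$A[, , , 1]
  d <- dim(sim$trials$data)
  p <- m$p_true
  Neff <- d[3] - p
  Ys <- matrix(0, d[1] * Neff, 10)
  Xs <- matrix(0, d[1] * Neff, 10 * p)
  for (r in seq_len(d[1])) {
    y <- sim$trials$data[r, , ]
    rows <- (r - 1) * Neff + seq_len(Neff)
    Ys[rows, ] <- t(y[, (p + 1):d[3]])
    for (k in seq_len(p)) {
      Xs[rows, (k - 1) * 10 + 1:10] <- t(y[, (p + 1 - k):(d[3] - k)])
    }
  }
  B <- stats::lm.fit(Xs, Ys)$coefficients
  for (q in seq_len(nrow(m$connections))) {
    cn <- m$connections[q, ]
    i <- match(cn$receiver, m$regions$name)
    j <- match(cn$sender, m$regions$name)
    est <- B[(cn$lag - 1) * 10 + j, i]
    tol <- if (cn$category == "input") 0.12 else 0.05
    expect_lt(abs(est - A_true[i, j, cn$lag]), tol)
  }
})

test_that("per-time-point source SNR calibration is honoured", {
  m <- default_model()
  sim <- simulate_trials(m, 150, seed = 9, keep_components = TRUE)
  pr <- source_snr_profile(sim)
  expect_lt(abs(pr$mean_ratio - 20) / 20, 0.1)
})
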