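# Shared lightweight fixtures, built once per test run.

.fx <- new.env()

small_head <- function(fold = 0) {
  key <- paste0("head_fold", fold)
  if (is.null(.fx[[key]])) {
    .fx[[key]] <- build_head_model(n_vertices = 160, n_electrodes = 24,
                                   fold_amplitude = fold)
  }
  .fx[[key]]
}

small_leadfield <- function(fold = 0) {
  key <- paste0("lf_fold", fold)
  if (is.null(.fx[[key]])) {
    hm <- small_head(fold)
    .fx[[key]] <- compute_leadfield(hm$head, hm$sources, hm$sensors)
  }
  .fx[[key]]
}

default_model <- function() {
  if (is.null(.fx$model)) .fx$model <- build_attention_model()
  .fx$model
}

# least-squares stationary MVAR fit (independent oracle for the Kalman
# trackers): regress y(n) on the p stacked past samples
ls_mvar_fit <- function(y, p) {
  m <- nrow(y); N <- ncol(y)
  Y <- t(y[, (p + 1):N, drop = FALSE])
  X <- matrix(0, N - p, m * p)
  for (k in seq_len(p)) {
    X[, (k - 1) * m + seq_len(m)] <- t(y[, (p + 1 - k):(N - k), drop = FALSE])
  }
  B <- stats::lm.fit(X, Y)$coefficients          # (m*p) x m
  A <- array(0, dim = c(m, m, p))
  for (k in seq_len(p)) A[, , k] <- t(B[(k - 1) * m + seq_len(m), , drop = FALSE])
  A
}

# simulate a stationary MVAR process with given coefficient array (m, m, p)
sim_mvar <- function(A, N, sd = 1, burn = 100) {
  m <- dim(A)[1]; p <- dim(A)[3]
  y <- matrix(0, m, N + burn)
  for (n in (p + 1):(N + burn)) {
    s <- rep(0, m)
    for (k in seq_len(p)) s <- s + A[, , k] %*% y[, n - k]
    y[, n] <- s + rnorm(m, sd = sd)
  }
  y[, (burn + 1):(N + burn), drop = FALSE]
}

# random stable time-invariant MVAR coefficient tensor (m, m, p, N)
random_stable_coeffs <- function(m, p, N, target_rho = 0.8) {
  A1 <- array(rnorm(m * m * p, sd = 0.3), dim = c(m, m, p))
  comp <- matrix(0, m * p, m * p)
  if (p > 1) comp[(m + 1):(m * p), 1:(m * (p - 1))] <- diag(m * (p - 1))
  for (k in seq_len(p)) comp[1:m, (k - 1) * m + 1:m] <- A1[, , k]
  rho <- max(Mod(eigen(comp, only.values = TRUE)$values))
  if (rho > target_rho) {
    for (k in seq_len(p)) A1[, , k] <- A1[, , k] * (target_rho / rho)^k
  }
  array(rep(A1, N), dim = c(m, m, p, N))
}
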