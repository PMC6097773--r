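#' Build a three-shell spherical head model with a quasi-cortical source mesh
#'
#' The head is modelled as three concentric spheres (brain, skull, skin) with
#' relative conductivities 1, 1/80 and 1 — the 1/80 skull/scalp ratio is the
#' pessimistic value that makes volume-conduction smearing most pronounced.
#' The source space is a subdivided icosahedron placed at a fraction of the
#' brain radius, optionally "folded" by a superposition of radial sinusoidal
#' perturbations so that outward normals vary in direction (and sign), as
#' cortical normals do. Electrodes are placed quasi-uniformly (Fibonacci
#' lattice) on the outer shell.
#'
#' @param n_vertices requested minimum number of source vertices; the actual
#'   mesh is the smallest icosphere refinement with at least this many
#' @param n_electrodes number of electrodes (>= 16)
#' @param fold_amplitude radial perturbation amplitude in mm (0 = smooth
#'   sphere, radial normals)
#' @param seed integer controlling the (fixed) orientation of the folding
#'   wave vectors
#' @param radii shell radii in mm (brain, skull, skin), strictly increasing
#' @param conductivities relative conductivities of the three shells
#' @param series_truncation number of terms of the spherical-harmonic series
#'   used for the lead field
#' @param src_radius_frac mean source-shell radius as a fraction of the brain
#'   radius
#' @param fold_freq angular frequency (radians^-1 on the unit sphere) of the
#'   folding pattern
#' @return list with elements `head` (class `head_model`), `sources` (class
#'   `source_space`: positions V x 3, unit `normals` V x 3, `triangles`
#'   F x 3) and `sensors` (class `sensor_array`: positions E x 3, labels)
#' @export
build_head_model <- function(n_vertices = 2000, n_electrodes = 64,
                             fold_amplitude = 0, seed = 1,
                             radii = c(80, 85, 92),
                             conductivities = c(1, 1 / 80, 1),
                             series_truncation = 60,
                             src_radius_frac = 0.75,
                             fold_freq = 30) {
  stopifnot(n_vertices >= 50, n_electrodes >= 16,
            length(radii) == 3, all(diff(radii) > 0),
            all(conductivities > 0))
  head <- structure(list(shell_radii = radii,
                         conductivities = conductivities,
                         series_truncation = series_truncation),
                    class = "head_model")

  mesh <- icosphere_mesh(n_vertices)
  r0 <- src_radius_frac * radii[1]

  # folding: r(u) = r0 + a * g(u), g a mean of three unit-amplitude
  # sinusoidal plane waves with pseudo-random (seed-fixed) directions
  set.seed(seed)
  W <- qr.Q(qr(matrix(rnorm(9), 3, 3)))      # random orthonormal directions
  g_and_grad <- function(U) {                # U: V x 3 unit directions
    ph <- fold_freq * (U %*% W)              # V x 3 phases
    g <- rowMeans(sin(ph))
    grad <- (cos(ph) %*% t(W)) * (fold_freq / 3)   # d g / d u (ambient)
    list(g = g, grad = grad)
  }
  gg <- g_and_grad(mesh$vertices)
  r_v <- r0 + fold_amplitude * gg$g
  if (any(r_v >= radii[1])) {
    stop("fold amplitude pushes vertices outside the brain shell")
  }
  positions <- mesh$vertices * r_v

  # normals from the implicit surface |x| - r0 - a g(x/|x|):
  # grad = u - (a / r) (I - u u^T) g'(u)
  tang <- gg$grad - mesh$vertices * rowSums(gg$grad * mesh$vertices)
  nrm <- mesh$vertices - (fold_amplitude / r_v) * tang
  nrm <- nrm / sqrt(rowSums(nrm^2))

  sources <- structure(list(positions = positions, normals = nrm,
                            triangles = mesh$triangles,
                            n_vertices = nrow(positions)),
                       class = "source_space")

  sensors <- structure(list(
    positions = fibonacci_sphere(n_electrodes) * radii[3],
    labels = sprintf("E%03d", seq_len(n_electrodes))),
    class = "sensor_array")

  list(head = head, sources = sources, sensors = sensors)
}

# subdivided icosahedron with at least n_vertices vertices
icosphere_mesh <- function(n_vertices) {
  t <- (1 + sqrt(5)) / 2
  v <- rbind(
    c(-1,  t, 0), c(1,  t, 0), c(-1, -t, 0), c(1, -t, 0),
    c(0, -1,  t), c(0, 1,  t), c(0, -1, -t), c(0, 1, -t),
    c( t, 0, -1), c(t, 0,  1), c(-t, 0, -1), c(-t, 0,  1))
  v <- v / sqrt(rowSums(v^2))
  f <- rbind(
    c(1, 12, 6), c(1, 6, 2), c(1, 2, 8), c(1, 8, 11), c(1, 11, 12),
    c(2, 6, 10), c(6, 12, 5), c(12, 11, 3), c(11, 8, 7), c(8, 2, 9),
    c(4, 10, 5), c(4, 5, 3), c(4, 3, 7), c(4, 7, 9), c(4, 9, 10),
    c(5, 10, 6), c(3, 5, 12), c(7, 3, 11), c(9, 7, 8), c(10, 9, 2))
  while (nrow(v) < n_vertices) {
    midcache <- new.env(hash = TRUE)
    nf <- matrix(0L, nrow(f) * 4, 3)
    vlist <- v
    midpoint <- function(a, b) {
      key <- paste(min(a, b), max(a, b))
      idx <- midcache[[key]]
      if (!is.null(idx)) return(idx)
      mp <- vlist[a, ] + vlist[b, ]
      mp <- mp / sqrt(sum(mp^2))
      vlist <<- rbind(vlist, mp)
      idx <- nrow(vlist)
      midcache[[key]] <- idx
      idx
    }
    for (i in seq_len(nrow(f))) {
      a <- f[i, 1]; b <- f[i, 2]; c_ <- f[i, 3]
      ab <- midpoint(a, b); bc <- midpoint(b, c_); ca <- midpoint(c_, a)
      nf[(i - 1) * 4 + 1:4, ] <- rbind(c(a, ab, ca), c(b, bc, ab),
                                       c(c_, ca, bc), c(ab, bc, ca))
    }
    v <- vlist
    f <- nf
  }
  list(vertices = v, triangles = f)
}

fibonacci_sphere <- function(n) {
  i <- seq_len(n) - 0.5
  z <- 1 - 2 * i / n
  phi <- pi * (1 + sqrt(5)) * i
  s <- sqrt(1 - z^2)
  cbind(s * cos(phi), s * sin(phi), z)
}

#' Compute the average-referenced lead field of the spherical head model
#'
#' Analytic series solution for the surface potential of a current dipole
#' inside three concentric conducting shells. Each source is a unit dipole
#' along its surface normal. After evaluation the matrix is average
#' referenced (column means over sensors removed) and globally rescaled so
#' that `mean(diag(G G^T)) = 1`, a unit convention that makes the
#' regularization parameter of the inverse step a relative quantity;
#' physical amplitudes are reintroduced by the scalp-projection scale factor.
#'
#' @param head a `head_model`
#' @param sources a `source_space`
#' @param sensors a `sensor_array`
#' @return object of class `lead_field`: list with `G` (E x V), `referenced`
#'   flag, and the truncation used
#' @export
compute_leadfield <- function(head, sources, sensors) {
  G <- leadfield_series(head, sources$positions, sources$normals,
                        sensors$positions, head$series_truncation)
  # average reference
  G <- sweep(G, 2, colMeans(G))
  G <- G * sqrt(nrow(G) / sum(G^2))
  structure(list(G = G, referenced = TRUE,
                 series_truncation = head$series_truncation),
            class = "lead_field")
}

# shared series evaluator; transfer = NULL uses the 3-shell transfer factors,
# transfer = "free" evaluates the unbounded-medium expansion (validation)
leadfield_series <- function(head, pos, mom, elec, n_terms,
                             transfer = NULL, check_convergence = TRUE) {
  r3 <- head$shell_radii[3]
  sigma1 <- head$conductivities[1]
  tn <- if (identical(transfer, "free")) {
    rep(1, n_terms)
  } else {
    shell_transfer(head, n_terms)
  }

  b <- sqrt(rowSums(pos^2))                       # dipole radii
  if (any(b >= r3)) stop("dipole outside the outer shell")
  bhat <- pos / pmax(b, .Machine$double.eps)
  deep <- b < .Machine$double.eps
  if (any(deep)) bhat[deep, ] <- matrix(c(0, 0, 1), sum(deep), 3, byrow = TRUE)
  ehat <- elec / sqrt(rowSums(elec^2))

  x <- ehat %*% t(bhat)                           # E x V: cos(gamma)
  x <- pmin(pmax(x, -1), 1)
  qr_ <- rowSums(mom * bhat)                      # radial moment component
  me <- ehat %*% t(mom)                           # E x V: m . e_hat
  tang <- me - sweep(x, 2, qr_, "*")              # q_t cos(beta) * sin(gamma)

  Pm1 <- matrix(1, nrow(x), ncol(x)); Pn <- x     # P_{n-1}, P_n
  Qm1 <- matrix(0, nrow(x), ncol(x)); Qn <- matrix(1, nrow(x), ncol(x))
  # Q_n = P_n^1 / sin(gamma):  Q_1 = 1, Q_2 = 3x
  ratio <- b / r3
  bpow <- rep(1 / (4 * pi * sigma1 * r3^2), length(b))  # b^{n-1}/(4 pi s1 r3^{n+1})
  G <- matrix(0, nrow(elec), nrow(pos))
  last_inc <- 0
  for (n in seq_len(n_terms)) {
    term <- sweep(Pn, 2, n * qr_, "*") + tang * Qn
    inc <- tn[n] * sweep(term, 2, bpow, "*")
    G <- G + inc
    last_inc <- max(abs(inc))
    if (n < n_terms) {
      Pp <- ((2 * n + 1) * x * Pn - n * Pm1) / (n + 1)
      Qp <- ((2 * n + 1) * x * Qn - (n + 1) * Qm1) / n
      Pm1 <- Pn; Pn <- Pp
      Qm1 <- Qn; Qn <- Qp
      bpow <- bpow * ratio            # b^{n-1}/r3^{n+1} -> b^n/r3^{n+2}
    }
  }
  if (check_convergence && last_inc > 1e-6 * max(abs(G))) {
    warning("lead-field series not converged after ", n_terms,
            " terms (relative last increment ",
            signif(last_inc / max(abs(G)), 3), ")")
  }
  G
}

# per-degree transfer factors of the three-shell sphere: the factor by which
# the n-th degree surface coefficient differs from the source coefficient of
# the unbounded medium. Equal conductivities give the closed form (2n+1)/n.
shell_transfer <- function(head, n_terms) {
  x1 <- head$shell_radii[1] / head$shell_radii[3]
  x2 <- head$shell_radii[2] / head$shell_radii[3]
  s <- head$conductivities
  vapply(seq_len(n_terms), function(n) {
    np1 <- n + 1
    # unknowns: A1, A2, B2, A3, B3 (source coefficient c = 1)
    M <- rbind(
      c(x1^n, -x1^n, -x1^-np1, 0, 0),
      c(s[1] * n * x1^(n - 1), -s[2] * n * x1^(n - 1),
        s[2] * np1 * x1^(-n - 2), 0, 0),
      c(0, x2^n, x2^-np1, -x2^n, -x2^-np1),
      c(0, s[2] * n * x2^(n - 1), -s[2] * np1 * x2^(-n - 2),
        -s[3] * n * x2^(n - 1), s[3] * np1 * x2^(-n - 2)),
      c(0, 0, 0, n, -np1))
    rhs <- c(-x1^-np1, s[1] * np1 * x1^(-n - 2), 0, 0, 0)
    u <- solve(M, rhs)
    u[4] + u[5]      # surface potential coefficient A3 + B3
  }, numeric(1))
}

#' Map ground-truth regions to their nearest source-mesh vertices
#'
#' Applies the packaged similarity transform from MNI mm into head-model mm
#' and returns, per region, the index of the mesh vertex with smallest
#' Euclidean distance to the mapped coordinate (ties broken by lowest index).
#'
#' @param sources a `source_space`
#' @param model a `gt_model`
#' @return integer vector of vertex indices, named by region; mapped
#'   coordinates attached as attribute `"mapped_xyz"`
#' @export
map_ground_truth_dipoles <- function(sources, model) {
  aff <- mni_affine()
  xyz <- as.matrix(model$regions[, c("x", "y", "z")])
  mapped <- sweep(xyz, 2, aff$center) * aff$scale
  idx <- vapply(seq_len(nrow(mapped)), function(i) {
    d2 <- rowSums(sweep(sources$positions, 2, mapped[i, ])^2)
    which.min(d2)   # which.min takes the first (lowest index) on ties
  }, integer(1))
  if (anyDuplicated(idx)) {
    stop("two regions map to the same mesh vertex; refine the mesh")
  }
  names(idx) <- model$regions$name
  attr(idx, "mapped_xyz") <- mapped
  idx
}

#' Project source trials to the scalp and add sensor noise
#'
#' Computes `D = scale * G * S + e` per trial. The white sensor noise
#' variance is set so that the ratio of the mean signal power (over all
#' trials, samples and electrodes) to the noise variance equals `scalp_snr`;
#' the noise is average re-referenced after addition so the data stay in the
#' reference subspace of the lead field.
#'
#' @param leadfield a `lead_field`
#' @param source_trials a `trial_tensor` whose channels are source dipoles
#' @param scalp_snr requested power signal-to-noise ratio (> 0)
#' @param scale overall source scale factor; `NULL` chooses it so the peak
#'   absolute noise-free scalp amplitude equals `target_peak`
#' @param seed optional integer seed for the noise draw
#' @param vertex_idx column indices of `G` corresponding to the channels of
#'   `source_trials`; `NULL` means the channels already span all columns
#' @param target_peak realistic peak amplitude (arbitrary units, default 50,
#'   i.e. tens of microvolts) used when `scale` is `NULL`
#' @return object of class `scalp_data`: list with `trials` (sensor-space
#'   `trial_tensor`), the noise-free `signal` array, `noise_sd`, `scale` and
#'   `scalp_snr`
#' @export
project_and_add_noise <- function(leadfield, source_trials, scalp_snr,
                                  scale = NULL, seed = NULL,
                                  vertex_idx = NULL, target_peak = 50) {
  stopifnot(inherits(source_trials, "trial_tensor"), scalp_snr > 0)
  G <- leadfield$G
  if (!is.null(vertex_idx)) G <- G[, vertex_idx, drop = FALSE]
  d <- dim(source_trials$data)
  stopifnot(ncol(G) == d[2])
  if (!is.null(seed)) set.seed(seed)

  E <- nrow(G)
  signal <- array(0, dim = c(d[1], E, d[3]))
  for (r in seq_len(d[1])) {
    signal[r, , ] <- G %*% source_trials$data[r, , ]
  }
  peak <- max(abs(signal))
  if (peak == 0) stop("source input has zero power; scalp SNR is undefined")
  if (is.null(scale)) scale <- target_peak / peak
  signal <- signal * scale

  noise_var <- mean(signal^2) / scalp_snr
  noise <- array(rnorm(length(signal), sd = sqrt(noise_var)), dim = dim(signal))
  # re-reference the noise: remove the per-sample mean across sensors
  noise <- sweep(noise, c(1, 3), apply(noise, c(1, 3), mean))
  data <- signal + noise

  structure(list(
    trials = trial_tensor(data, fs = source_trials$fs,
                          t0_ms = source_trials$t0_ms,
                          channels = sprintf("E%03d", seq_len(E))),
    signal = signal, noise_sd = sqrt(noise_var),
    scale = scale, scalp_snr = scalp_snr
  ), class = "scalp_data")
}
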