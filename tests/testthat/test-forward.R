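test_that("source mesh is a closed surface with controllable normals", {
  hm <- small_head(fold = 0)
  src <- hm$sources
  # unfolded: normals exactly radial
  rad <- src$positions / sqrt(rowSums(src$positions^2))
  expect_lt(max(abs(rowSums(src$normals * rad) - 1)), 1e-9)

  # Euler characteristic V - E + F = 2
  tri <- src$triangles
  ed <- unique(t(apply(rbind(tri[, 1:2], tri[, 2:3], tri[, c(3, 1)]), 1, sort)))
  expect_equal(nrow(src$positions) - nrow(ed) + nrow(tri), 2)

  # folding at 0.15 * source radius makes some adjacent normals disagree
  hmf <- small_head(fold = 9)
  nn <- hmf$sources$normals
  trif <- hmf$sources$triangles
  edf <- unique(t(apply(rbind(trif[, 1:2], trif[, 2:3], trif[, c(3, 1)]),
                        1, sort)))
  expect_lt(min(rowSums(nn[edf[, 1], ] * nn[edf[, 2], ])), 0)

  expect_error(build_head_model(160, 24, fold_amplitude = 30),
               "outside the brain shell")
})

test_that("three-shell series matches closed forms", {
  # equal conductivities: transfer factor has the closed form (2n+1)/n
  head_eq <- structure(list(shell_radii = c(80, 85, 92),
                            conductivities = c(1, 1, 1),
                            series_truncation = 60), class = "head_model")
  tn <- tvconnsim:::shell_transfer(head_eq, 12)
  expect_equal(tn, (2 * (1:12) + 1) / (1:12), tolerance = 1e-12)

  # unbounded-medium series reproduces the analytic dipole potential
  set.seed(7)
  pos <- matrix(c(10, 20, 30, -25, 5, 40, 0, 0, 55), 3, 3, byrow = TRUE)
  mom <- matrix(rnorm(9), 3, 3)
  mom <- mom / sqrt(rowSums(mom^2))
  elec <- matrix(rnorm(24), 8, 3)
  elec <- elec / sqrt(rowSums(elec^2)) * 92
  Gser <- tvconnsim:::leadfield_series(head_eq, pos, mom, elec, 200,
                                       transfer = "free",
                                       check_convergence = FALSE)
  Gan <- matrix(0, 8, 3)
  for (v in 1:3) {
    for (e in 1:8) {
      d <- elec[e, ] - pos[v, ]
      Gan[e, v] <- sum(mom[v, ] * d) / (4 * pi * sum(d^2)^1.5)
    }
  }
  expect_lt(max(abs(Gser - Gan)) / max(abs(Gan)), 1e-10)
})

test_that("lead field is referenced, converged and physically sensible", {
  hm <- small_head(fold = 0)
  lf <- small_leadfield(fold = 0)
  expect_true(lf$referenced)
  expect_lt(max(abs(colSums(lf$G))), 1e-10 * max(sqrt(colSums(lf$G^2))))

  # doubling the series truncation barely changes the raw series
  G1 <- tvconnsim:::leadfield_series(hm$head, hm$sources$positions,
                                     hm$sources$normals,
                                     hm$sensors$positions, 60)
  G2 <- tvconnsim:::leadfield_series(hm$head, hm$sources$positions,
                                     hm$sources$normals,
                                     hm$sensors$positions, 120)
  expect_lt(max(abs(G1 - G2)) / max(abs(G1)), 1e-6)

  # mirror symmetry: x-mirrored dipoles and electrodes give equal gains
  pos <- matrix(c(30, 10, 40), 1, 3)
  mom <- matrix(c(0.2, 0.5, sqrt(1 - 0.04 - 0.25)), 1, 3)
  el <- matrix(c(50, 20, 73, -50, 20, 73), 2, 3, byrow = TRUE)
  el <- el / sqrt(rowSums(el^2)) * 92
  mir <- function(x) { x[, 1] <- -x[, 1]; x }
  Ga <- tvconnsim:::leadfield_series(hm$head, pos, mom, el, 80,
                                     check_convergence = FALSE)
  Gb <- tvconnsim:::leadfield_series(hm$head, mir(pos), mir(mom), mir(el), 80,
                                     check_convergence = FALSE)
  expect_equal(Ga, Gb, tolerance = 1e-12)

  # gain at the closest electrode decays monotonically with dipole depth
  el_top <- matrix(c(0, 0, 92), 1, 3)
  radii <- seq(70, 10, by = -10)
  pos_line <- cbind(0, 0, radii)
  mom_line <- matrix(rep(c(0, 0, 1), length(radii)), ncol = 3, byrow = TRUE)
  Gd <- tvconnsim:::leadfield_series(hm$head, pos_line, mom_line, el_top, 80,
                                     check_convergence = FALSE)
  expect_true(all(diff(abs(as.numeric(Gd))) < 0))
})

test_that("ground-truth regions map to distinct nearest vertices", {
  hm <- small_head(fold = 9)
  m <- default_model()
  idx <- map_ground_truth_dipoles(hm$sources, m)
  expect_length(unique(idx), 10)

  # brute-force nearest-neighbour oracle
  mapped <- attr(idx, "mapped_xyz")
  for (g in seq_len(10)) {
    d2 <- rowSums(sweep(hm$sources$positions, 2, mapped[g, ])^2)
    expect_equal(unname(idx[g]), unname(which.min(d2)))
  }

  # vertices exactly at the mapped coordinates are their own neighbours
  fake <- hm$sources
  fake$positions <- rbind(mapped, mapped + 40)
  fake$n_vertices <- nrow(fake$positions)
  idx2 <- map_ground_truth_dipoles(fake, m)
  expect_equal(as.vector(unname(idx2)), 1:10)
})

test_that("scalp projection calibrates the requested SNR", {
  hm <- small_head(fold = 0)
  lf <- small_leadfield(fold = 0)
  m <- default_model()
  sim <- simulate_trials(m, 20, seed = 3)
  idx <- map_ground_truth_dipoles(hm$sources, m)

  # infinite SNR: no noise at all, D = scale * G * S
  clean <- project_and_add_noise(lf, sim$trials, Inf, vertex_idx = idx,
                                 seed = 1)
  expect_equal(clean$trials$data, clean$signal)
  expect_equal(max(abs(clean$signal)), 50)   # default target peak

  scalp <- project_and_add_noise(lf, sim$trials, 5, vertex_idx = idx,
                                 seed = 1)
  noise <- scalp$trials$data - scalp$signal
  realized <- mean(scalp$signal^2) / mean(noise^2)
  expect_lt(abs(realized - 5) / 5, 0.05)

  # average reference: per-sample sensor mean vanishes
  expect_lt(max(abs(apply(scalp$trials$data, c(1, 3), mean))), 1e-10)

  zero <- sim$trials
  zero$data[] <- 0
  expect_error(project_and_add_noise(lf, zero, 5, vertex_idx = idx),
               "zero power")
})
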