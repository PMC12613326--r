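test_that("Velocity-Verlet steps are exact for free and constant-force motion", {
  ## zero force: uniform linear motion
  st <- nuclear_step(R = 1, v = 0.02, masses = 2000, force = 0,
                     force_fn = function(R) 0, dt = 10)
  expect_equal(st$R, 1 + 0.02 * 10)
  expect_equal(st$v, 0.02)

  ## constant force f: R gains v dt + f dt^2 / (2m) exactly
  f <- 0.003
  st2 <- nuclear_step(R = 0, v = 0, masses = 2000, force = f,
                      force_fn = function(R) f, dt = 10)
  expect_equal(st2$R, 0.5 * f * 100 / 2000)
  expect_equal(st2$v, f * 10 / 2000)
  expect_error(nuclear_step(0, 0, 1, NaN, function(R) 0, 1),
               "non-finite")
})

test_that("Velocity-Verlet conserves harmonic energy over 1e4 steps", {
  mu <- 2000; omega <- 0.01
  k <- mu * omega^2
  dt <- 5e-4 / omega   # symplectic error bound (omega dt)^2/8 ~ 3e-8
  R <- 0.4; v <- 0
  force <- -k * R
  e0 <- 0.5 * k * R^2
  for (s in seq_len(1e4)) {
    st <- nuclear_step(R, v, mu, force, function(x) -k * x, dt)
    R <- st$R; v <- st$v; force <- st$force
  }
  e1 <- 0.5 * k * R^2 + 0.5 * mu * v^2
  expect_lt(abs(e1 - e0) / e0, 1e-7)
})

test_that("finite-difference NAC reproduces the rotation closed form", {
  W0 <- diag(2)
  th <- 0.01
  W1 <- matrix(c(cos(th), sin(th), -sin(th), cos(th)), 2, 2)
  ov <- electronic_overlap_and_nac(W0, W1, dt = 1)
  expect_equal(ov$K,
               matrix(c(1 - cos(th), sin(th), -sin(th), 1 - cos(th)), 2, 2))
  expect_equal(ov$K[1, 2], -sin(0.01), tolerance = 1e-12)
  expect_equal(ov$K[1, 1], (1 - cos(0.01)) / 1, tolerance = 1e-12)

  ov0 <- electronic_overlap_and_nac(W1, W1, dt = 0.5)
  expect_equal(ov0$K, matrix(0, 2, 2), tolerance = 1e-14)
  expect_error(electronic_overlap_and_nac(diag(2), diag(3), 1),
               "dimension mismatch")
})

test_that("sign continuity flips inverted eigenvector columns", {
  W0 <- diag(2)
  W1 <- diag(c(-1, 1))
  ov <- electronic_overlap_and_nac(W0, W1, dt = 1)
  expect_equal(ov$W_now, diag(2))
  expect_equal(ov$S, diag(2))
})

test_that("local diabatization returns the closest orthogonal matrix", {
  expect_equal(local_diabatization_matrix(diag(3)), diag(3))
  th <- 0.3
  Q <- matrix(c(cos(th), sin(th), -sin(th), cos(th)), 2, 2)
  expect_equal(local_diabatization_matrix(Q), Q, tolerance = 1e-14)

  ## noisy orthogonal input: compare against the symmetric-orthogonalization
  ## oracle U = S (S^T S)^{-1/2} computed by eigendecomposition
  set.seed(10)
  for (rep in seq_len(20)) {
    S <- Q + matrix(rnorm(4, sd = 1e-3), 2, 2)
    U <- local_diabatization_matrix(S)
    expect_lt(max(abs(crossprod(U) - diag(2))), 1e-12)
    es <- eigen(crossprod(S), symmetric = TRUE)
    inv_sqrt <- es$vectors %*% (1 / sqrt(es$values) * t(es$vectors))
    expect_equal(U, S %*% inv_sqrt, tolerance = 1e-10)
    expect_lt(max(abs(U - S)), 1e-2)
  }
  expect_error(local_diabatization_matrix(matrix(0, 2, 2)), "singular")
})

test_that("electronic substeps reproduce phases and Rabi oscillations", {
  ## constant diagonal: pure phases
  E <- c(0.02, 0.05)
  c0 <- c(1, 1i) / sqrt(2)
  ct <- electronic_substep_propagation(c0, diag(E), diag(E), dt = 50,
                                       n_substeps = 51)
  expect_equal(ct, c0 * exp(-1i * E * 50), tolerance = 1e-6)  # RK4 order

  ## two-state constant coupling: cos^2/sin^2 populations
  V <- matrix(c(0, 0.001, 0.001, 0), 2, 2)
  ct2 <- electronic_substep_propagation(c(1, 0), V, V, dt = 100,
                                        n_substeps = 51)
  expect_equal(Mod(ct2)^2, c(cos(0.001 * 100)^2, sin(0.001 * 100)^2),
               tolerance = 1e-8)

  ## zero Hamiltonian: unchanged
  z <- matrix(0, 2, 2)
  expect_equal(electronic_substep_propagation(c0, z, z, dt = 10), c0)
})

test_that("density-flux hop probabilities follow the stated formula", {
  expect_equal(hop_probabilities(c(0.6, 0.4), c(0.6, 0.4), 1), c(0, 0))
  expect_equal(hop_probabilities(c(0.6, 0.3, 0.1), c(0.5, 0.4, 0.1), 1),
               c(0, 1 / 6, 0))
  expect_equal(hop_probabilities(c(0.6, 0.2, 0.2), c(0.5, 0.25, 0.25), 1),
               c(0, 1 / 12, 1 / 12))
  ## zero active population: all zero
  expect_equal(hop_probabilities(c(0, 1), c(0, 1), 1), c(0, 0))
  ## probabilities sum to at most one
  set.seed(11)
  for (rep in seq_len(200)) {
    r0 <- abs(rnorm(3)); r0 <- r0 / sum(r0)
    r1 <- abs(rnorm(3)); r1 <- r1 / sum(r1)
    expect_lte(sum(hop_probabilities(r0, r1, 1)), 1 + 1e-12)
  }
})

test_that("hop attempts respect frustration and rescale factors", {
  expect_equal(hop_rescale_factor(0, 0.01), 1)
  expect_equal(hop_rescale_factor(0.0025, 0.01), sqrt(0.75))
  expect_equal(hop_rescale_factor(0.0025, 0.01), 0.866025, tolerance = 1e-6)
  expect_error(hop_rescale_factor(2, 1), "frustrated")

  ## target gap exceeds kinetic energy: frustrated, nothing changes
  ah <- attempt_hop(1, c(0, 1), r = 0.5, energies = c(0, 0.2), T = 0.1)
  expect_false(ah$hopped)
  expect_true(ah$frustrated)
  expect_equal(ah$active, 1)

  ah2 <- attempt_hop(1, c(0, 0.4), r = 0.3, energies = c(0, 0.05), T = 0.1)
  expect_true(ah2$hopped)
  expect_equal(ah2$active, 2)
  ah3 <- attempt_hop(1, c(0, 0.4), r = 0.9, energies = c(0, 0.05), T = 0.1)
  expect_false(ah3$hopped)
  expect_false(ah3$frustrated)
})

test_that("zero-coupling trajectories keep populations and conserve energy", {
  m <- sloped_uncoupled_model(k1 = 0.002, k2 = -0.001, gap = 0.03)
  cfg <- integrator_config(dt = fs_to_au(0.1),
                           n_steps = ceiling(fs_to_au(100) / fs_to_au(0.1)))
  tr <- run_trajectory(m, R0 = 0, p0 = 5, coefficients = c(1, 0),
                       basis = "adiabatic", config = cfg, seed = 1)
  expect_false(tr$failed)
  expect_equal(nrow(tr$hops), 0L)
  pops <- Mod(tr$coefficients)^2
  expect_lt(max(abs(pops[, 1] - 1)), 1e-10)
  expect_lt(max(abs(tr$energy - tr$energy[1])), 1e-6)
})

test_that("trajectories are exactly reproducible for a given seed", {
  m <- build_model("avoided_crossing_2s")
  cfg <- integrator_config(dt = fs_to_au(0.1), n_steps = 200)
  deco <- decoherence_config("fmi", sigma = 0.22, mu = 2000)
  t1 <- run_trajectory(m, 2.3, 0, c(1, 0), config = cfg, deco = deco,
                       seed = 31)
  t2 <- run_trajectory(m, 2.3, 0, c(1, 0), config = cfg, deco = deco,
                       seed = 31)
  expect_identical(t1$positions, t2$positions)
  expect_identical(t1$coefficients, t2$coefficients)
  expect_identical(t1$active, t2$active)
  expect_identical(t1$hops, t2$hops)
})

test_that("compiled and reference engines propagate identically", {
  m <- build_model("ibr_surrogate_3s")
  cfg <- integrator_config(dt = fs_to_au(0.1), n_steps = 80)
  for (variant in c("nd", "edc", "fmi")) {
    deco <- if (variant == "fmi") {
      decoherence_config("fmi", sigma = 0.069, mu = 89380)
    } else decoherence_config(variant)
    a <- run_trajectory(m, 4.6, 3, c(0, 1, 1i) / sqrt(2), config = cfg,
                        deco = deco, seed = 17, engine = "cpp")
    b <- run_trajectory(m, 4.6, 3, c(0, 1, 1i) / sqrt(2), config = cfg,
                        deco = deco, seed = 17, engine = "r")
    expect_equal(a$active, b$active)
    expect_lt(max(abs(a$coefficients - b$coefficients)), 1e-9)
    expect_lt(max(abs(a$positions - b$positions)), 1e-11)
    expect_lt(max(abs(a$p_aux - b$p_aux)), 1e-8)
  }
})

test_that("coefficient norm and diabatization unitarity hold along trajectories", {
  m <- build_model("avoided_crossing_2s")
  cfg <- integrator_config(dt = fs_to_au(0.1), n_steps = 350)
  deco <- decoherence_config("fmi", sigma = 0.22, mu = 2000)
  tr <- run_trajectory(m, 2.3, 0, c(1, 0), config = cfg, deco = deco,
                       seed = 5)
  norms <- rowSums(Mod(tr$coefficients)^2)
  expect_lt(max(abs(norms - 1)), 1e-10)
})

test_that("total energy is exactly compensated at hops", {
  m <- build_model("avoided_crossing_2s")
  cfg <- integrator_config(dt = fs_to_au(0.1), n_steps = 350)
  found <- FALSE
  for (seed in 1:30) {
    tr <- run_trajectory(m, 2.3, 0, c(1, 0), config = cfg,
                         deco = decoherence_config("nd"), seed = seed)
    if (sum(tr$hops$frustrated == 0) > 0) found <- TRUE
    ## energy continuous through hops: drift stays at integrator level
    expect_lt(max(abs(tr$energy - tr$energy[1])), 1e-5)
  }
  expect_true(found)   # the crossing actually produces hops
})

test_that("zero NAC leaves adiabatic populations untouched in many dimensions", {
  m <- lvc_uncoupled_model(gap = 0.05, slopes1 = c(0.002, 0.001, 0.003),
                           slopes2 = c(0.002, 0.001, 0.003))
  cfg <- integrator_config(dt = fs_to_au(0.2), n_steps = 200)
  tr <- run_trajectory(m, R0 = c(3, -2, 1), p0 = c(0.1, 0, -0.2),
                       coefficients = c(1, 1) / sqrt(2),
                       config = cfg, deco = decoherence_config("nd"),
                       seed = 2)
  pops <- Mod(tr$coefficients)^2
  expect_lt(max(abs(pops[, 1] - pops[1, 1])), 1e-9)
  expect_equal(nrow(tr$hops), 0L)
})
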