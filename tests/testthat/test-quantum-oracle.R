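test_that("Fourier-grid ground state reproduces the harmonic oscillator", {
  m <- harmonic_model(mu = 2000, omega = 0.01)
  gs <- fourier_grid_ground_state(m, 1)
  expect_equal(gs$energy, 0.005, tolerance = 1e-8 / 0.005)
  wf <- gs$wavefunction
  expect_equal(wf_norm(wf), 1, tolerance = 1e-10)
  sdx <- sqrt(sum(wf$x^2 * abs(wf$psi[, 1])^2) * wf$dx)
  expect_equal(sdx, 1 / sqrt(2 * 2000 * 0.01), tolerance = 1e-6)
  expect_true(all(Re(wf$psi[, 1]) >= 0))
})

test_that("unbound potentials are rejected by the edge-amplitude check", {
  m <- diabatic_model(2, masses = 2000, terms = list(
    list(i = 1, j = 1, type = "exp", A = 0.05, a = 1, x0 = 0),
    list(i = 2, j = 2, type = "const", c = 1)
  ))
  m$grid <- c(0, 10, 256)
  expect_error(fourier_grid_ground_state(m, 1), "unbound|grid too small")
})

test_that("coherent state follows the classical oscillation", {
  mu <- 2000; omega <- 0.01
  m <- harmonic_model(mu = mu, omega = omega)
  sig <- 1 / sqrt(2 * mu * omega)
  x0 <- 0.3
  wf <- promote_wavefunction(
    grid_gaussian(seq(-1.5, 1.5, length.out = 512), x0, sig), c(1, 0))
  dt <- fs_to_au(0.005)
  period <- 2 * pi / omega
  n <- ceiling(period / dt)
  ser <- split_operator_propagate(wf, m, dt, n, save_every = 50)
  for (s in ser$snapshots) {
    xm <- sum(s$x * abs(s$psi[, 1])^2) * s$dx
    expect_lt(abs(xm - x0 * cos(omega * s$time)), 1e-6)
  }
})

test_that("free Gaussian spreads with the analytic variance", {
  mu <- 2000
  m <- flat_coupled_model(v12 = 0, gap = 1)
  sig0 <- 0.4
  wf <- promote_wavefunction(
    grid_gaussian(seq(-20, 20, length.out = 512), 0, sig0), c(1, 0))
  dt <- fs_to_au(0.05)
  ser <- split_operator_propagate(wf, m, dt, 2000, save_every = 400)
  for (s in ser$snapshots) {
    v <- sum(s$x^2 * abs(s$psi[, 1])^2) * s$dx
    expect_lt(abs(v - (sig0^2 + s$time^2 / (4 * mu^2 * sig0^2))), 1e-6)
  }
})

test_that("two flat coupled surfaces Rabi-oscillate exactly", {
  v12 <- 0.005
  m <- flat_coupled_model(v12 = v12, gap = 0)
  wf <- promote_wavefunction(
    grid_gaussian(seq(-20, 20, length.out = 256), 0, 1), c(1, 0))
  ser <- split_operator_propagate(wf, m, dt = 1, n_steps = 600,
                                  save_every = 60)
  for (s in ser$snapshots) {
    p1 <- sum(abs(s$psi[, 1])^2) * s$dx
    expect_lt(abs(p1 - cos(v12 * s$time)^2), 1e-8)
  }
})

test_that("norm is conserved over 1e4 steps on the shipped presets", {
  for (nm in c("avoided_crossing_2s", "ibr_surrogate_3s")) {
    m <- build_model(nm)
    m$grid <- c(m$grid[1], m$grid[2], 512)
    wf <- initial_wavefunction(m)
    ser <- suppressWarnings(
      split_operator_propagate(wf, m, dt = fs_to_au(0.01),
                               n_steps = 10000, save_every = 2500))
    norms <- vapply(ser$snapshots, wf_norm, numeric(1))
    expect_lt(max(abs(norms - norms[1])), 1e-10)
  }
})

test_that("total energy is conserved on a closed system", {
  ## Strang-splitting energy error is O(dt^2); at dt = 0.01 au the bound is
  ## well below the 1e-8 relative target
  mu <- 2000; omega <- 0.01
  m <- harmonic_model(mu = mu, omega = omega)
  sig <- 1 / sqrt(2 * mu * omega)
  wf <- promote_wavefunction(
    grid_gaussian(seq(-1.5, 1.5, length.out = 256), 0.2, sig), c(1, 0))
  ser <- split_operator_propagate(wf, m, dt = 0.01, n_steps = 10000,
                                  save_every = 2000)
  obs <- grid_observables(ser, m)
  expect_lt(max(abs(obs$energy - obs$energy[1])) / abs(obs$energy[1]), 1e-8)
})

test_that("propagation error is second order in the time step", {
  mu <- 2000; omega <- 0.01
  m <- harmonic_model(mu = mu, omega = omega)
  sig <- 1 / sqrt(2 * mu * omega)
  x <- seq(-1.5, 1.5, length.out = 256)
  wf <- promote_wavefunction(grid_gaussian(x, 0.3, sig), c(1, 0))
  tend <- 400
  final_x <- function(dt) {
    s <- split_operator_propagate(wf, m, dt, round(tend / dt),
                                  save_every = round(tend / dt))
    sn <- s$snapshots[[length(s$snapshots)]]
    sum(sn$x * abs(sn$psi[, 1])^2) * sn$dx
  }
  ref <- final_x(0.5)
  e1 <- abs(final_x(4) - ref)
  e2 <- abs(final_x(2) - ref)
  expect_gt(e1 / e2, 3.0)   # halving dt reduces the error ~4x
  expect_lt(e1 / e2, 5.0)
})

test_that("grid observables implement the overlap-weighted coherences", {
  m <- flat_coupled_model(v12 = 0, gap = 0.2)
  x <- seq(-20, 20, length.out = 256)
  g <- grid_gaussian(x, 0, 1)

  single <- promote_wavefunction(g, c(1, 0))
  obs <- grid_observables(
    structure(list(times = 0, snapshots = list(single), x = x,
                   dx = g$dx), class = "grid_wf_series"), m)
  expect_equal(obs$pop_d1, 1, tolerance = 1e-10)
  expect_lt(abs(obs$re_rho12) + abs(obs$im_rho12), 1e-10)

  ## equal superposition with identical nuclear factors: rho_12 = 0.5
  both <- promote_wavefunction(g, c(1, 1))
  obs2 <- grid_observables(
    structure(list(times = 0, snapshots = list(both), x = x,
                   dx = g$dx), class = "grid_wf_series"), m)
  expect_equal(obs2$re_rho12, 0.5, tolerance = 1e-10)
  expect_equal(obs2$s_abs12, 1, tolerance = 1e-10)

  ## non-overlapping nuclear factors: coherence vanishes regardless of c
  apart <- grid_wavefunction(x, cbind(grid_gaussian(x, -8, 0.5)$psi,
                                      grid_gaussian(x, 8, 0.5)$psi) /
                                  sqrt(2))
  obs3 <- grid_observables(
    structure(list(times = 0, snapshots = list(apart), x = x,
                   dx = g$dx), class = "grid_wf_series"), m)
  expect_lt(abs(obs3$re_rho12) + abs(obs3$im_rho12), 1e-10)
})
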