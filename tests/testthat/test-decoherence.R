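test_that("EDC rate matches its closed form and limits", {
  expect_equal(edc_rate(0.5, 0, 0.1), 0)
  expect_equal(edc_rate(0.1, 0.1, 0.1), 0.05)
  expect_equal(edc_rate(0.1, 1e6 * 0.1, 0.1), 0.1, tolerance = 1e-6)
})

test_that("FM and PFM rates evaluate their printed examples", {
  expect_equal(fm_rate_1d(0, 3, 1, 1), 0)
  expect_equal(fm_rate_1d(1, 0, 1, 1), 0.5)
  expect_equal(fm_rate_1d(2, 3, 1, 1), 0.5 * (6 + 2 * sqrt(10)))
  expect_equal(fm_rate_1d(2, 3, 1, 1), 6.162278, tolerance = 1e-6)

  expect_equal(pfm_rate(0, 5, 1, 8), 0)
  expect_equal(pfm_rate(1, 0, 1, 8), pi)
  expect_equal(pfm_rate(1, 1, 2, 2), pi^2 / 16 + pi / sqrt(2))
  expect_equal(pfm_rate(1, 1, 2, 2), 2.838291, tolerance = 1e-6)

  expect_equal(fm_rate_normal_modes(c(0, 0), c(1, 2), c(1, 1)), 0)
})

test_that("the 1-D rate is the single-mode mass-weighted normal-mode rate", {
  set.seed(4)
  for (rep in seq_len(200)) {
    mu <- runif(1, 100, 1e5)
    sigma <- runif(1, 0.01, 2)
    p <- rnorm(1, sd = 20); f <- rnorm(1, sd = 0.05)
    omega <- 1 / (2 * mu * sigma^2)
    k1 <- fm_rate_1d(p, f, sigma, mu)
    k2 <- fm_rate_normal_modes(p / sqrt(mu), f / sqrt(mu), omega)
    ## machine precision relative to the magnitude of the summed terms
    ## (k itself may vanish by cancellation)
    scale <- sigma^2 / 2 *
      (abs(p * f) + abs(p) * sqrt(f^2 + 1 / (mu^2 * sigma^6)))
    expect_lt(abs(k1 - k2), 1e-12 * max(1, scale))
  }
})

test_that("the common-frequency expression bounds the normal-mode rate", {
  set.seed(5)
  for (rep in seq_len(10000)) {
    nd <- sample(1:12, 1)
    omega <- runif(1, 1e-4, 1e-1)
    qd <- rnorm(nd, sd = 10^runif(1, -3, 1))
    qdd <- rnorm(nd, sd = 10^runif(1, -4, 0))
    expect_lte(fm_rate_normal_modes(qd, qdd, rep(omega, nd)),
               fm_rate_common_omega_bound(qd, qdd, omega) + 1e-14)
  }
})

test_that("all decoherence rates are non-negative under random inputs", {
  set.seed(6)
  n <- 1e5
  p <- rnorm(n, sd = 50); f <- rnorm(n, sd = 0.1)
  expect_true(all(fm_rate_1d(p, f, 0.3, 2000) >= 0))
  expect_true(all(pfm_rate(abs(p), abs(f), 0.005, 6) >= 0))
  expect_true(all(edc_rate(abs(rnorm(n)), abs(rnorm(n)), 0.1) >= 0))
  qd <- rnorm(20); qdd <- rnorm(20)
  expect_gte(fm_rate_normal_modes(qd, qdd, runif(20, 0.001, 0.1)), 0)
})

test_that("TVP auxiliary forces follow the thresholded forward difference", {
  expect_equal(tvp_force(0, 0.01, v = 0.5, dt = 10), -0.002)
  expect_equal(tvp_force(0.3, 0.3, v = 0.5, dt = 10), 0)
  expect_equal(tvp_force(0, 0.01, v = 1e-10, dt = 10, kappa = 1e-9), 0)
  ## vectorized over states, signed velocity
  expect_equal(tvp_force(c(0, 1), c(0.01, 1), v = -0.5, dt = 10),
               c(0.002, 0))
})

test_that("auxiliary momentum updates implement slaving, injection and continuity", {
  ## equal initial momenta for all above-threshold states: FM/PFM rates vanish
  deco <- decoherence_config("fm", sigma = 0.1, mu = 2000)
  k <- decoherence_rates(deco, active = 1, p_aux = c(7, 7, 7),
                         aux_forces = c(0, 0, 0), energies = c(0, 1, 2))
  expect_equal(k, c(0, 0, 0))

  ## subthreshold slaving: P_a = 10, E_ia = 0.75 T -> P_i = 5
  out <- aux_momentum_update(p_aux = c(10, 0), aux_forces = c(0, 0),
                             pop_old = c(1, 0), pop_new = c(1, 0),
                             energies_new = c(0, 0.75), T_new = 1,
                             active_new = 1, active_old = 1, dt = 1)
  expect_equal(out[2], 5)

  ## injection blend: P_i = 4*(1 - 0.5) + 0.5*8 = 6
  out2 <- aux_momentum_update(p_aux = c(8, 4), aux_forces = c(0, 0),
                              pop_old = c(0.9, 0.1), pop_new = c(0.8, 0.2),
                              energies_new = c(0, 0), T_new = 1,
                              active_new = 1, active_old = 1, dt = 1,
                              injection = TRUE)
  expect_equal(out2[2], 6)
  ## without injection the same step just propagates
  out3 <- aux_momentum_update(p_aux = c(8, 4), aux_forces = c(0, 0.5),
                              pop_old = c(0.9, 0.1), pop_new = c(0.8, 0.2),
                              energies_new = c(0, 0), T_new = 1,
                              active_new = 1, active_old = 1, dt = 1)
  expect_equal(out3[2], 4.5)

  ## active continuity across a hop with rescaling
  out4 <- aux_momentum_update(p_aux = c(10, 3), aux_forces = c(0.2, 0.1),
                              pop_old = c(0.5, 0.5), pop_new = c(0.5, 0.5),
                              energies_new = c(0, 0), T_new = 2,
                              active_new = 2, active_old = 1,
                              hop_factor = 0.5, dt = 1)
  expect_equal(out4[2], (10 + 0.1) * 0.5)
})

test_that("decoherence damping preserves norm and never inflates inactive states", {
  ## the printed two-state example: damping factor 0.5 in amplitude
  c0 <- sqrt(c(0.5, 0.5))
  dt <- 1
  k <- c(log(2), 0)       # e^{-k dt} = 0.5 for the inactive state 1
  out <- apply_decoherence(c0, k, active = 2, dt = dt)
  expect_equal(Mod(out)^2, c(0.125, 0.875), tolerance = 1e-12)

  expect_equal(apply_decoherence(c0, c(0, 0), 2, 1), as.complex(c0))

  out_inf <- apply_decoherence(c0, c(1e9, 0), 2, 1)
  expect_equal(Mod(out_inf)^2, c(0, 1), tolerance = 1e-12)

  set.seed(8)
  for (rep in seq_len(300)) {
    ns <- sample(2:4, 1)
    cc <- complex(real = rnorm(ns), imaginary = rnorm(ns))
    cc <- cc / sqrt(sum(Mod(cc)^2))
    a <- sample(ns, 1)
    if (Mod(cc[a]) < 1e-3) next
    k <- abs(rnorm(ns, sd = 2)); k[a] <- 0
    out <- apply_decoherence(cc, k, a, dt = runif(1, 0, 2))
    expect_equal(sum(Mod(out)^2), 1, tolerance = 1e-12)
    expect_true(all(Mod(out[-a])^2 <= Mod(cc[-a])^2 + 1e-14))
  }

  ## threshold collapse moves the residual to the active state
  cc <- as.complex(sqrt(c(5e-5, 1 - 5e-5)))
  out <- apply_decoherence(cc, c(0, 0), active = 2, dt = 1, eta = 1e-4,
                           pop_prev = c(2e-4, 1 - 2e-4))
  expect_equal(Mod(out)^2, c(0, 1), tolerance = 1e-12)
  expect_error(apply_decoherence(c(1, 0), c(1, 0), active = 2, dt = 1),
               "ill-posed")
})

test_that("decoherence configs validate their required parameters", {
  expect_error(decoherence_config("fm", sigma = NULL, mu = 2000),
               "requires positive sigma")
  expect_error(decoherence_config("pfm", omega = 0.01, n_d = NULL),
               "requires positive n_d")
  expect_error(decoherence_config("edc", C = -1), "requires positive C")
  d <- decoherence_config("fmi", sigma = 0.1, mu = 100)
  expect_true(d$injection)
  expect_equal(d$eta, 1e-4)
  expect_equal(d$kappa, 1e-9)
})
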