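test_that("ensembles are reproducible and independent of execution order", {
  m <- build_model("avoided_crossing_2s")
  ens <- sample_initial_conditions(m, 10, seed = 3)
  cfg <- integrator_config(dt = fs_to_au(0.1), n_steps = 100)
  deco <- decoherence_config("fmi", sigma = 0.22, mu = 2000)
  raw1 <- run_ensemble(m, ens, cfg, deco, base_seed = 50)
  raw2 <- run_ensemble(m, ens, cfg, deco, base_seed = 50)
  for (nu in seq_len(10)) {
    expect_identical(raw1$trajectories[[nu]]$coefficients,
                     raw2$trajectories[[nu]]$coefficients)
  }
  ## order independence: trajectory nu only depends on its own seed
  solo <- run_trajectory(m, ens$positions[7, ], ens$momenta[7, ],
                         ens$coefficients[7, ], basis = "diabatic",
                         config = cfg, deco = deco, seed = 50 + 7)
  expect_identical(solo$coefficients, raw1$trajectories[[7]]$coefficients)
  expect_identical(solo$active, raw1$trajectories[[7]]$active)
})

## minimal fake trajectory for filtering/balancing tests
fake_traj <- function(a0, drift = 0, failed = FALSE, nt = 5) {
  structure(list(times = seq(0, 1, length.out = nt),
                 active = rep(as.integer(a0), nt),
                 coefficients = matrix(rep(as.complex(a0 == 1:2), each = nt),
                                       nt, 2),
                 energy = c(0, rep(drift, nt - 1)),
                 failed = failed, hops = data.frame()),
            class = "tsh_trajectory")
}
fake_raw <- function(trajs) {
  structure(list(trajectories = trajs, n = length(trajs), base_seed = 1,
                 deco = "nd", dt = 1, model_name = "fake"),
            class = "tsh_ensemble_raw")
}

test_that("filtering keeps compliant ensembles untouched", {
  raw <- fake_raw(c(replicate(5, fake_traj(1), simplify = FALSE),
                    replicate(5, fake_traj(2), simplify = FALSE)))
  out <- filter_and_balance(raw, E_D = 0.01, seed = 1)
  expect_identical(out$counts,
                   c(run = 10L, valid = 10L, balanced = 10L))
  expect_length(out$removed, 0)
  ## infinite threshold likewise
  out2 <- filter_and_balance(raw, E_D = Inf, seed = 1)
  expect_equal(out2$n, 10)
})

test_that("balancing restores the initial active fractions after exclusion", {
  ## 5 started on surface A (all valid), 5 on surface B (only 3 valid):
  ## B is the max-failure surface, ~2 A-trajectories must be removed
  trajs <- c(replicate(5, fake_traj(1), simplify = FALSE),
             replicate(3, fake_traj(2), simplify = FALSE),
             replicate(2, fake_traj(2, drift = 1), simplify = FALSE))
  out <- filter_and_balance(fake_raw(trajs), E_D = 0.5, seed = 4)
  expect_identical(out$counts[["valid"]], 8L)
  expect_identical(out$counts[["balanced"]], 6L)
  a0 <- vapply(out$trajectories, function(tr) tr$active[1], integer(1))
  expect_equal(mean(a0 == 1), 0.5, tolerance = 1 / (2 * 6))
  expect_error(
    filter_and_balance(fake_raw(list(fake_traj(1, drift = 2))), E_D = 1),
    "all trajectories excluded")
})

test_that("ensemble averages reproduce hand-computed density matrices", {
  tr1 <- fake_traj(1); tr2 <- fake_traj(2)
  res <- ensemble_averages(fake_raw(list(tr1, tr2)))
  expect_equal(res$populations[1, ], c(0.5, 0.5))
  expect_equal(Re(res$rho[1, 1, 2]), 0)
  ## every trajectory active on its own fully populated state: gap = 0
  expect_equal(max(res$gap), 0)

  ## all trajectories in the same superposition: Re rho_12 = 0.5
  sup <- fake_traj(1)
  sup$coefficients <- matrix((1 + 0i) / sqrt(2), 5, 2)
  res2 <- ensemble_averages(fake_raw(list(sup, sup)))
  expect_equal(Re(res2$rho[1, 1, 2]), 0.5)
  expect_error(ensemble_averages(fake_raw(list(tr1))), "at least 2")
})

test_that("averaged density matrices keep unit trace and Cauchy-Schwarz", {
  m <- build_model("avoided_crossing_2s")
  ens <- sample_initial_conditions(m, 30, seed = 13,
                                   coefficients = c(1, 1i))
  cfg <- integrator_config(dt = fs_to_au(0.1), n_steps = 150,
                           record_every = 5)
  raw <- run_ensemble(m, ens, cfg, decoherence_config("nd"), base_seed = 77)
  res <- ensemble_averages(raw)
  tr_rho <- rowSums(res$populations)
  expect_lt(max(abs(tr_rho - 1)), 1e-10)
  bound <- sqrt(res$populations[, 1] * res$populations[, 2])
  expect_true(all(abs(res$rho[, 1, 2]) <= bound + 1e-12))
  ## per-trajectory Cauchy-Schwarz is an identity for pure states
  cc <- raw$trajectories[[1]]$coefficients
  expect_equal(abs(cc[, 1] * Conj(cc[, 2])),
               sqrt(Mod(cc[, 1])^2 * Mod(cc[, 2])^2), tolerance = 1e-12)
})

test_that("without decoherence an initial coherence only dephases", {
  ## 50/50 superposition on two uncoupled surfaces of different slope:
  ## per-trajectory coherence magnitude stays 0.5, the ensemble average decays
  m <- sloped_uncoupled_model(k1 = 0.004, k2 = -0.004, gap = 0.02)
  m$initial <- list(type = "gaussian", x0 = 0, sigma = 0.3, p0 = 0,
                    diabatic_coefficients = c(1, 1) / sqrt(2))
  ens <- sample_initial_conditions(m, 60, seed = 19)
  cfg <- integrator_config(dt = fs_to_au(0.1), n_steps = 400,
                           record_every = 4)
  raw <- run_ensemble(m, ens, cfg, decoherence_config("nd"), base_seed = 19)
  res <- ensemble_averages(raw)
  nt <- length(res$times)
  for (tr in raw$trajectories[1:5]) {
    coh <- abs(tr$coefficients[, 1] * Conj(tr$coefficients[, 2]))
    expect_lt(max(abs(coh - 0.5)), 1e-9)
  }
  expect_equal(abs(res$rho[1, 1, 2]), 0.5, tolerance = 1e-9)
  expect_lt(abs(res$rho[nt, 1, 2]), 0.1)
})

test_that("observable expectations use the full electronic wave function", {
  m <- build_model("avoided_crossing_2s")
  ens <- sample_initial_conditions(m, 6, seed = 23)
  cfg <- integrator_config(dt = fs_to_au(0.1), n_steps = 20,
                           record_every = 10)
  raw <- run_ensemble(m, ens, cfg, decoherence_config("nd"), base_seed = 23)
  res <- ensemble_averages(raw, model = m, observables = TRUE)
  expect_true(!is.null(res$observables$dipole))
  ## hand-computed check at t = 0 for the first trajectory set
  acc <- 0
  for (tr in raw$trajectories) {
    W <- adiabatize(m, R = tr$positions[1, ])$W
    O <- t(W) %*% m$operators$dipole(tr$positions[1, ]) %*% W
    cc <- tr$coefficients[1, ]
    acc <- acc + Re(crossprod(Conj(cc), O %*% cc))
  }
  expect_equal(res$observables$dipole[1], as.numeric(acc) / 6, tolerance = 1e-12)
})
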