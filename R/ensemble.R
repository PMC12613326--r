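#' Sample initial conditions according to a model's preset protocol
#'
#' Materializes the model's `initial` metadata as a phase-space ensemble:
#' `"gaussian"` presets sample the analytic Wigner distribution of the
#' minimum-uncertainty packet (position ~ N(x0, sigma^2), momentum ~
#' N(p0, 1/(4 sigma^2))); `"ground_state"` presets compute the numerical
#' ground state of the reference diabat and sample its gridded Wigner
#' distribution with the configured floor; `"harmonic_wigner"` presets use
#' the model's normal modes.
#'
#' @param model a [diabatic_model()] with `initial` metadata
#' @param n number of samples
#' @param seed RNG seed
#' @param coefficients optional complex diabatic amplitudes overriding the
#'   preset's initial electronic state
#' @param floor Wigner floor for grid sampling (default `1e-10`)
#' @return an [initial_ensemble()] (diabatic-basis coefficients)
#' @export
sample_initial_conditions <- function(model, n, seed, coefficients = NULL,
                                      floor = 1e-10) {
  ini <- model$initial
  if (is.null(ini)) stop("model carries no initial-state metadata")
  if (is.null(coefficients)) coefficients <- ini$diabatic_coefficients
  if (ini$type == "gaussian") {
    set.seed(seed)
    xs <- stats::rnorm(n, ini$x0, ini$sigma)
    ps <- stats::rnorm(n, ini$p0, 1 / (2 * ini$sigma))
    initial_ensemble(matrix(xs, ncol = 1), matrix(ps, ncol = 1),
                     coefficients, seed = seed)
  } else if (ini$type == "ground_state") {
    wf <- fourier_grid_ground_state(model, ini$ref_state)$wavefunction
    grid_wigner_sample(wf, n, seed, floor = floor,
                       coefficients = coefficients)
  } else if (ini$type == "harmonic_wigner") {
    harmonic_wigner_sample(model$normal_modes, n, seed,
                           coefficients = coefficients)
  } else {
    stop("unknown initial-state type: ", ini$type)
  }
}

#' Run an ensemble of independent surface-hopping trajectories
#'
#' Propagates one trajectory per row of the initial ensemble.  Trajectory
#' \eqn{\nu} is seeded with `base_seed + nu`, so every trajectory is
#' statistically independent, the result does not depend on execution order,
#' and repeated runs are identical.  Failing trajectories are kept as flagged
#' records and do not abort the ensemble.
#'
#' @param model a [diabatic_model()]
#' @param ensemble an [initial_ensemble()]
#' @param config an [integrator_config()]
#' @param deco a [decoherence_config()]
#' @param base_seed integer base seed
#' @param engine `"cpp"` or `"r"` (see [run_trajectory()])
#' @return object of class `tsh_ensemble_raw`: list of `tsh_trajectory`
#'   objects plus run metadata
#' @export
run_ensemble <- function(model, ensemble, config,
                         deco = decoherence_config("nd"),
                         base_seed = 1L, engine = "cpp") {
  deco <- .deco_resolve(deco, model)
  trajs <- vector("list", ensemble$n)
  for (nu in seq_len(ensemble$n)) {
    trajs[[nu]] <- run_trajectory(
      model, R0 = ensemble$positions[nu, ], p0 = ensemble$momenta[nu, ],
      coefficients = ensemble$coefficients[nu, ], basis = ensemble$basis,
      config = config, deco = deco, seed = base_seed + nu, engine = engine)
  }
  structure(list(trajectories = trajs, n = ensemble$n,
                 base_seed = base_seed, deco = deco$variant,
                 dt = config$dt, model_name = model$name),
            class = "tsh_ensemble_raw")
}

#' @export
print.tsh_ensemble_raw <- function(x, ...) {
  nf <- sum(vapply(x$trajectories, function(tr) tr$failed, logical(1)))
  cat(sprintf("<tsh_ensemble_raw> %d trajectories (%d failed), deco = %s, base seed %d\n",
              x$n, nf, x$deco, x$base_seed))
  invisible(x)
}

#' Energy-drift filtering and stochastic ensemble balancing
#'
#' Excludes trajectories whose total energy drifts by more than `E_D` from
#' its initial value at any recorded time (and failed trajectories).  When an
#' initial coherent superposition populates several surfaces, exclusion
#' probabilities may differ between the surfaces on which trajectories were
#' started; to mitigate the bias, the initial-surface fractions of the
#' surviving ensemble are rebalanced: the initially populated surface with the
#' highest failure probability is identified and trajectories started on the
#' other surfaces are removed at random until the time-zero fractions of
#' active trajectories again match the original ones (to within half a
#' trajectory).
#'
#' @param raw a `tsh_ensemble_raw` from [run_ensemble()]
#' @param E_D energy-drift threshold in hartree (default 1.0 eV)
#' @param seed RNG seed for the stochastic removal
#' @return a `tsh_ensemble_raw` containing the balanced valid trajectories,
#'   with components `counts` (run/valid/balanced) and `removed` added
#' @export
filter_and_balance <- function(raw, E_D = 1.0 / ev_per_hartree, seed = 1L) {
  drift <- vapply(raw$trajectories, function(tr) {
    if (tr$failed) Inf else max(abs(tr$energy - tr$energy[1]))
  }, numeric(1))
  valid <- drift <= E_D
  if (!any(valid)) stop("all trajectories excluded by the energy-drift filter")
  a0 <- vapply(raw$trajectories, function(tr) tr$active[1], integer(1))
  states <- sort(unique(a0))
  pi0 <- vapply(states, function(j) mean(a0 == j), numeric(1))
  piv <- vapply(states, function(j) mean(a0[valid] == j), numeric(1))
  keep <- which(valid)
  removed <- integer(0)
  if (length(states) > 1L && any(!valid)) {
    k <- which.max(pi0 - piv)
    n_k <- sum(a0[keep] == states[k])
    if (n_k > 0) {
      n_target <- n_k / pi0[k]
      set.seed(seed)
      for (jj in seq_along(states)) {
        if (jj == k) next
        idx_j <- keep[a0[keep] == states[jj]]
        want <- round(pi0[jj] * n_target)
        if (length(idx_j) > want) {
          drop_j <- sample(idx_j, length(idx_j) - want)
          removed <- c(removed, drop_j)
        }
      }
      keep <- setdiff(keep, removed)
    }
  }
  out <- raw
  out$trajectories <- raw$trajectories[keep]
  out$n <- length(keep)
  out$counts <- c(run = length(drift), valid = sum(valid),
                  balanced = length(keep))
  storage.mode(out$counts) <- "integer"
  out$removed <- removed
  out$E_D <- E_D
  out
}

#' Ensemble averages, coherences and internal-consistency diagnostics
#'
#' Averages the per-trajectory electronic density matrices,
#' \eqn{\rho_{ij}(t) = \langle c_i^\nu(t) c_j^{\nu*}(t)\rangle_\nu}, computes
#' the fractions of active trajectories \eqn{\Pi_j(t)}, the
#' internal-consistency gap \eqn{g(t) = \max_j |\rho_{jj}(t) - \Pi_j(t)|},
#' 95% confidence intervals (normal approximation, mean +- 1.96 SE), and --
#' when a model with operators is given -- observable expectations using the
#' full electronic wave function,
#' \eqn{\langle O\rangle(t) = \langle \sum_{ij} c_i^* c_j\,
#' O_{ij}(R^\nu(t))\rangle_\nu} with the operator matrix transformed to the
#' adiabatic basis at each trajectory geometry.
#'
#' @param raw a (filtered/balanced) `tsh_ensemble_raw`
#' @param model optional [diabatic_model()]; needed only for operator
#'   expectations
#' @param observables logical: evaluate model operator expectations (can be
#'   slow for large ensembles)
#' @return object of class `tsh_ensemble` with elements `times`,
#'   `populations`, `populations_ci`, `pi_fraction`, `rho` (complex array
#'   time x state x state), `rho_re_ci`, `gap`, `counts`, `energy0`,
#'   `observables`
#' @export
ensemble_averages <- function(raw, model = NULL, observables = FALSE) {
  trajs <- Filter(function(tr) !tr$failed, raw$trajectories)
  n <- length(trajs)
  if (n < 2) stop("need at least 2 valid trajectories on a common time grid")
  times <- trajs[[1]]$times
  for (tr in trajs) {
    if (length(tr$times) != length(times) || max(abs(tr$times - times)) > 0) {
      stop("mismatched time grids between trajectories")
    }
  }
  nt <- length(times)
  ns <- ncol(trajs[[1]]$coefficients)
  rho <- array(0i, c(nt, ns, ns))
  pop <- matrix(0, nt, ns)
  pop_se <- matrix(0, nt, ns)
  rho_re_se <- array(0, c(nt, ns, ns))
  pi_frac <- matrix(0, nt, ns)
  ## accumulate sums and sums of squares
  s_rho <- array(0i, c(nt, ns, ns))
  s_re2 <- array(0, c(nt, ns, ns))
  s_pop2 <- matrix(0, nt, ns)
  for (tr in trajs) {
    cc <- tr$coefficients
    for (i in seq_len(ns)) {
      pii <- Mod(cc[, i])^2
      s_pop2[, i] <- s_pop2[, i] + pii^2
      for (j in seq_len(ns)) {
        x <- cc[, i] * Conj(cc[, j])
        s_rho[, i, j] <- s_rho[, i, j] + x
        s_re2[, i, j] <- s_re2[, i, j] + Re(x)^2
      }
      pi_frac[, i] <- pi_frac[, i] + (tr$active == i)
    }
  }
  rho <- s_rho / n
  pi_frac <- pi_frac / n
  for (i in seq_len(ns)) {
    pop[, i] <- Re(rho[, i, i])
    pop_se[, i] <- sqrt(pmax(0, s_pop2[, i] / n - pop[, i]^2) / n)
    for (j in seq_len(ns)) {
      rho_re_se[, i, j] <-
        sqrt(pmax(0, s_re2[, i, j] / n - Re(rho[, i, j])^2) / n)
    }
  }
  gap <- apply(abs(pop - pi_frac), 1, max)
  obs <- NULL
  if (observables && !is.null(model) && !is.null(model$operators)) {
    obs <- list()
    for (nm in names(model$operators)) {
      op <- model$operators[[nm]]
      acc <- numeric(nt)
      for (tr in trajs) {
        for (ti in seq_len(nt)) {
          Rpt <- tr$positions[ti, ]
          W <- adiabatize(model, R = Rpt)$W
          Oad <- t(W) %*% op(Rpt) %*% W
          cc <- tr$coefficients[ti, ]
          acc[ti] <- acc[ti] + Re(crossprod(Conj(cc), Oad %*% cc))
        }
      }
      obs[[nm]] <- acc / n
    }
  }
  structure(list(times = times, populations = pop,
                 populations_ci = 1.96 * pop_se, pi_fraction = pi_frac,
                 rho = rho, rho_re_ci = 1.96 * rho_re_se, gap = gap,
                 counts = raw$counts %||% c(run = raw$n, valid = n,
                                            balanced = n),
                 energy0 = vapply(trajs, function(tr) tr$energy[1],
                                  numeric(1)),
                 n = n, deco = raw$deco, base_seed = raw$base_seed,
                 observables = obs),
            class = "tsh_ensemble")
}

#' @export
print.tsh_ensemble <- function(x, ...) {
  ns <- ncol(x$populations)
  nt <- length(x$times)
  cat(sprintf("<tsh_ensemble> %d trajectories, %d states, t up to %.3f fs (deco = %s)\n",
              x$n, ns, au_to_fs(max(x$times)), x$deco))
  cat("  final adiabatic populations:",
      paste(sprintf("%.4f", x$populations[nt, ]), collapse = ", "), "\n")
  cat("  final active fractions:     ",
      paste(sprintf("%.4f", x$pi_fraction[nt, ]), collapse = ", "), "\n")
  cat(sprintf("  internal-consistency gap: max %.4f, time-avg %.4f\n",
              max(x$gap), mean(x$gap)))
  invisible(x)
}

#' @export
summary.tsh_ensemble <- function(object, ...) {
  print(object)
  cat(sprintf("  counts: run %d, valid %d, balanced %d\n",
              object$counts["run"], object$counts["valid"],
              object$counts["balanced"]))
  cat(sprintf("  initial total energy: %.6f +- %.6f hartree\n",
              mean(object$energy0), stats::sd(object$energy0)))
  invisible(object)
}

#' @export
as.data.frame.tsh_ensemble <- function(x, ...) {
  ns <- ncol(x$populations)
  df <- data.frame(time = x$times, time_fs = au_to_fs(x$times))
  for (j in seq_len(ns)) {
    df[[paste0("rho", j, j)]] <- x$populations[, j]
    df[[paste0("pi", j)]] <- x$pi_fraction[, j]
  }
  for (i in seq_len(ns - 1)) for (j in (i + 1):ns) {
    df[[paste0("re_rho", i, j)]] <- Re(x$rho[, i, j])
    df[[paste0("im_rho", i, j)]] <- Im(x$rho[, i, j])
    df[[paste0("re_rho", i, j, "_ci")]] <- x$rho_re_ci[, i, j]
  }
  df$gap <- x$gap
  df
}

#' Plot ensemble populations, active fractions and a coherence
#' @param x a `tsh_ensemble`
#' @param pair state pair whose coherence to draw (default `c(1, 2)`)
#' @param ... passed to [graphics::matplot()]
#' @export
plot.tsh_ensemble <- function(x, pair = c(1, 2), ...) {
  tfs <- au_to_fs(x$times)
  old <- graphics::par(mfrow = c(2, 1), mar = c(4, 4, 1, 1))
  on.exit(graphics::par(old))
  graphics::matplot(tfs, x$populations, type = "l", lty = 1,
                    xlab = "t [fs]", ylab = expression(rho[jj]), ...)
  graphics::matlines(tfs, x$pi_fraction, lty = 3)
  graphics::plot(tfs, Re(x$rho[, pair[1], pair[2]]), type = "l",
                 xlab = "t [fs]",
                 ylab = sprintf("Re rho_%d%d", pair[1], pair[2]))
  invisible(x)
}

#' Full pipeline: sample, propagate, filter, balance, average
#'
#' Convenience wrapper running the complete protocol on a preset model:
#' initial-condition sampling, `n` trajectories with the requested
#' decoherence variant, energy-drift filtering with stochastic balancing, and
#' ensemble averaging.  Decoherence width parameters are derived from the
#' sampled ensemble (1-D: sample standard deviation of the bond coordinate)
#' or the model's normal modes (multi-D: geometric-mean frequency) when not
#' given.
#'
#' @param model a [diabatic_model()] (typically from [build_model()])
#' @param n ensemble size
#' @param variant decoherence variant (see [decoherence_config()])
#' @param seed base seed; sampling uses `seed`, trajectories `seed + nu`,
#'   balancing `seed + 1`
#' @param t_max_fs,dt_fs propagation horizon and nuclear step in fs (defaults
#'   from the model metadata)
#' @param coefficients optional diabatic amplitudes overriding the preset
#' @param eta,record_every,E_D further knobs (see the respective functions)
#' @param hop_scheme see [integrator_config()]
#' @return a `tsh_ensemble`
#' @export
tsh_simulation <- function(model, n, variant = "fmi", seed = 1L,
                           t_max_fs = NULL, dt_fs = NULL,
                           coefficients = NULL, eta = 1e-4,
                           record_every = 5L,
                           E_D = 1.0 / ev_per_hartree,
                           hop_scheme = "density_flux") {
  if (is.null(t_max_fs)) t_max_fs <- model$defaults$t_max_fs
  if (is.null(dt_fs)) dt_fs <- model$defaults$dt_fs
  ens <- sample_initial_conditions(model, n, seed,
                                   coefficients = coefficients)
  deco <- if (variant %in% c("fm", "fmi")) {
    ws <- width_parameters(ens, mu = model$masses[1])
    decoherence_config(variant, sigma = ws$sigma, mu = ws$mu, eta = eta)
  } else if (variant %in% c("pfm", "pfmi")) {
    ws <- width_parameters(model$normal_modes)
    decoherence_config(variant, omega = ws$omega, n_d = ws$n_d, eta = eta)
  } else {
    decoherence_config(variant, eta = eta)
  }
  dt <- fs_to_au(dt_fs)
  cfg <- integrator_config(dt = dt, n_steps = ceiling(fs_to_au(t_max_fs) / dt),
                           record_every = record_every,
                           hop_scheme = hop_scheme)
  raw <- run_ensemble(model, ens, cfg, deco, base_seed = seed)
  bal <- filter_and_balance(raw, E_D = E_D, seed = seed + 1L)
  ensemble_averages(bal)
}

#' Maximum deviation between TSH ensemble and grid-propagation populations
#'
#' Interpolates the quantum adiabatic populations onto the ensemble's time
#' grid and reports the largest absolute population deviation, overall and at
#' the final common time.
#'
#' @param ens a `tsh_ensemble`
#' @param grid_obs data frame from [grid_observables()]
#' @return list with `max_dev`, `final_dev`, and the aligned population
#'   matrices
#' @export
compare_to_grid <- function(ens, grid_obs) {
  ns <- ncol(ens$populations)
  tmax <- min(max(ens$times), max(grid_obs$time))
  tt <- ens$times[ens$times <= tmax + 1e-9]
  qpop <- sapply(seq_len(ns), function(j) {
    stats::approx(grid_obs$time, grid_obs[[paste0("pop_a", j)]],
                  xout = tt)$y
  })
  tpop <- ens$populations[seq_along(tt), , drop = FALSE]
  dev <- abs(tpop - qpop)
  list(max_dev = max(dev), final_dev = max(dev[length(tt), ]),
       times = tt, tsh = tpop, quantum = qpop)
}
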