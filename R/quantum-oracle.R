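#' Multi-state wavefunction on an equidistant grid
#'
#' Container for the exact quantum reference: complex nuclear amplitudes per
#' diabatic state, tabulated on an equidistant one-dimensional grid.
#'
#' @param x equidistant grid points (bohr)
#' @param psi complex matrix, `length(x)` rows, one column per diabatic state
#' @param time time stamp (atomic units)
#' @return object of class `grid_wavefunction`
#' @export
grid_wavefunction <- function(x, psi, time = 0) {
  x <- as.numeric(x)
  dx <- diff(x)
  if (max(abs(dx - dx[1])) > 1e-9 * abs(dx[1])) {
    stop("grid must be equidistant")
  }
  psi <- as.matrix(psi)
  if (nrow(psi) != length(x)) stop("psi must have one row per grid point")
  structure(list(x = x, dx = dx[1], psi = psi, time = time),
            class = "grid_wavefunction")
}

#' @export
print.grid_wavefunction <- function(x, ...) {
  cat(sprintf("<grid_wavefunction> %d points on [%.3g, %.3g] bohr, %d state(s), t = %.4g a.u., norm = %.10f\n",
              length(x$x), min(x$x), max(x$x), ncol(x$psi), x$time,
              wf_norm(x)))
  invisible(x)
}

#' Total norm of a grid wavefunction
#' @param wf a [grid_wavefunction()]
#' @return \eqn{\sum_j \sum_k |\psi_j(x_k)|^2 \Delta x}
#' @export
wf_norm <- function(wf) sum(abs(wf$psi)^2) * wf$dx

.resolve_grid <- function(model, grid_spec) {
  if (is.null(grid_spec)) grid_spec <- model$grid
  if (is.null(grid_spec)) grid_spec <- c(3.5, 11, 1024)
  seq(grid_spec[1], grid_spec[2], length.out = as.integer(grid_spec[3]))
}

#' Ground state of a single diabatic surface by Fourier-grid diagonalization
#'
#' Diagonalizes the single-surface Hamiltonian
#' \eqn{-\tfrac{1}{2\mu}\partial_x^2 + V_{jj}(x)} on the equidistant grid
#' using the sinc-DVR (Colbert-Miller) kinetic matrix and returns the lowest
#' eigenpair.  The wavefunction is made real, positive and unit-norm.  If the
#' resulting state is not localized well inside the grid (edge amplitude above
#' `1e-8`), the potential is unbound on the grid or the grid is too small and
#' an error is raised.
#'
#' @param model a 1-dof [diabatic_model()]
#' @param state diabatic state index whose diagonal potential is used
#' @param grid_spec `c(xmin, xmax, n)` or `NULL` to use the model's default
#' @return list with `wavefunction` (a [grid_wavefunction()] populating only
#'   column `state`... see Details) and `energy` (hartree).  The returned
#'   wavefunction has a single column; use [promote_wavefunction()] to place
#'   it on several surfaces.
#' @export
fourier_grid_ground_state <- function(model, state = 1, grid_spec = NULL) {
  if (model$n_dof != 1L) stop("grid methods require a 1-dof model")
  x <- .resolve_grid(model, grid_spec)
  n <- length(x)
  dx <- x[2] - x[1]
  mu <- model$masses[1]
  Vd <- vapply(x, function(xx) model_potential(model, xx)[state, state],
               numeric(1))
  ## sinc-DVR kinetic energy matrix
  idx <- seq_len(n)
  dmat <- outer(idx, idx, "-")
  Tm <- (-1)^dmat * (2 / dmat^2)
  diag(Tm) <- pi^2 / 3
  Tm <- Tm / (2 * mu * dx^2)
  H <- Tm + diag(Vd)
  e <- eigen(H, symmetric = TRUE)
  k0 <- which.min(e$values)
  psi0 <- e$vectors[, k0]
  psi0 <- psi0 / sqrt(sum(psi0^2) * dx)
  if (sum(psi0) < 0) psi0 <- -psi0   # nodeless ground state: global sign only
  edge <- max(abs(psi0[1]), abs(psi0[n]))
  if (edge > 1e-8) {
    stop("ground state not localized on the grid (edge amplitude ",
         format(edge, digits = 3),
         "): unbound potential or grid too small")
  }
  list(wavefunction = grid_wavefunction(x, matrix(psi0, ncol = 1)),
       energy = e$values[k0])
}

#' Place a single-surface nuclear function on several diabatic surfaces
#'
#' Builds an initial coherent superposition by copying one nuclear amplitude
#' onto every diabatic state with the given complex weights,
#' \eqn{\tilde\psi_j(x) = c_j\,\psi_0(x)}; the weights are normalized.
#'
#' @param wf a single-column [grid_wavefunction()]
#' @param coefficients complex weights, one per diabatic state of the target
#'   model (e.g. `c(0, 1, 1)/sqrt(2)`)
#' @return a multi-column [grid_wavefunction()]
#' @export
promote_wavefunction <- function(wf, coefficients) {
  coefficients <- as.complex(coefficients)
  nrm <- sqrt(sum(abs(coefficients)^2))
  if (nrm == 0) stop("all-zero coefficients")
  coefficients <- coefficients / nrm
  psi <- wf$psi[, 1]
  grid_wavefunction(wf$x, outer(psi, coefficients), wf$time)
}

#' Gaussian wave packet on a grid
#'
#' Minimum-uncertainty Gaussian \eqn{(2\pi\sigma^2)^{-1/4}
#' e^{-(x-x_0)^2/(4\sigma^2)} e^{i p_0 x}} with position spread `sigma`.
#'
#' @param x grid points, or `c(xmin, xmax, n)` spec
#' @param x0 centre (bohr); `sigma` position standard deviation (bohr);
#'   `p0` momentum centre (a.u.)
#' @param sigma,p0 see above
#' @return single-column [grid_wavefunction()]
#' @export
grid_gaussian <- function(x, x0, sigma, p0 = 0) {
  if (length(x) == 3 && x[3] > 3) x <- seq(x[1], x[2], length.out = x[3])
  psi <- (2 * pi * sigma^2)^(-1 / 4) *
    exp(-(x - x0)^2 / (4 * sigma^2)) * exp(1i * p0 * x)
  grid_wavefunction(x, matrix(psi, ncol = 1))
}

#' Default initial wavefunction of a preset model
#'
#' Materializes the model's `initial` metadata: either an analytic Gaussian or
#' the Fourier-grid ground state of a reference diabat, promoted onto the
#' diabatic surfaces with the stored (or overriding) complex coefficients.
#'
#' @param model a 1-dof [diabatic_model()] with `initial` metadata
#' @param grid_spec optional grid override `c(xmin, xmax, n)`
#' @param coefficients optional complex diabatic weights overriding the preset
#' @return a multi-column [grid_wavefunction()]
#' @export
initial_wavefunction <- function(model, grid_spec = NULL, coefficients = NULL) {
  ini <- model$initial
  if (is.null(ini)) stop("model carries no initial-state metadata")
  if (is.null(coefficients)) coefficients <- ini$diabatic_coefficients
  if (ini$type == "gaussian") {
    x <- .resolve_grid(model, grid_spec)
    wf <- grid_gaussian(x, ini$x0, ini$sigma, ini$p0)
  } else if (ini$type == "ground_state") {
    wf <- fourier_grid_ground_state(model, ini$ref_state, grid_spec)$wavefunction
  } else {
    stop("initial-state type not grid-representable: ", ini$type)
  }
  promote_wavefunction(wf, coefficients)
}

#' Exact quantum propagation by the split-operator method
#'
#' Propagates the coupled diabatic nuclear amplitudes with symmetric Strang
#' splitting,
#' \eqn{e^{-iV\Delta t/2}\, \mathcal{F}^{-1} e^{-iT\Delta t} \mathcal{F}\,
#' e^{-iV\Delta t/2}},
#' applying the potential half-steps through pointwise diagonalization of the
#' diabatic matrix (precomputed once, since the potential is static) and the
#' kinetic step in Fourier space.  Propagation is carried out entirely in the
#' diabatic representation.
#'
#' @param wf initial [grid_wavefunction()] (all diabatic states as columns)
#' @param model the 1-dof [diabatic_model()]
#' @param dt time step, atomic units
#' @param n_steps number of steps
#' @param save_every store every `save_every`-th step (default chosen to keep
#'   about 200 snapshots); the initial and final states are always stored
#' @return object of class `grid_wf_series`: list with `times`, `snapshots`
#'   (list of [grid_wavefunction()]), `x`, `dx`
#' @export
split_operator_propagate <- function(wf, model, dt, n_steps,
                                     save_every = NULL) {
  stopifnot(dt > 0, n_steps >= 1)
  if (is.null(save_every)) save_every <- max(1L, floor(n_steps / 200))
  x <- wf$x; n <- length(x); dx <- wf$dx
  ns <- model$n_states
  if (ncol(wf$psi) != ns) stop("wavefunction/model state count mismatch")
  mu <- model$masses[1]

  ## potential half-step propagators, one ns x ns complex matrix per point
  Phalf <- array(0i, c(ns, ns, n))
  for (k in seq_len(n)) {
    V <- model_potential(model, x[k])
    e <- eigen(V, symmetric = TRUE)
    Phalf[, , k] <- e$vectors %*% (exp(-1i * e$values * dt / 2) *
                                     t(e$vectors))
  }
  ## vectorized application: psi_i <- sum_j Phalf[i,j,] * psi_j
  Pij <- lapply(seq_len(ns), function(i)
    lapply(seq_len(ns), function(j) Phalf[i, j, ]))
  kvec <- 2 * pi / (n * dx) * c(0:(n %/% 2 - 1), -(n %/% 2):-1)
  kin_phase <- exp(-1i * kvec^2 / (2 * mu) * dt)

  apply_v <- function(psi) {
    out <- matrix(0i, n, ns)
    for (i in seq_len(ns)) {
      acc <- 0i
      for (j in seq_len(ns)) acc <- acc + Pij[[i]][[j]] * psi[, j]
      out[, i] <- acc
    }
    out
  }
  psi <- wf$psi
  times <- wf$time
  snapshots <- list(grid_wavefunction(x, psi, wf$time))
  edge_warned <- FALSE
  for (s in seq_len(n_steps)) {
    psi <- apply_v(psi)
    for (j in seq_len(ns)) {
      psi[, j] <- stats::fft(kin_phase * stats::fft(psi[, j]),
                             inverse = TRUE) / n
    }
    psi <- apply_v(psi)
    if (s %% save_every == 0L || s == n_steps) {
      tnow <- wf$time + s * dt
      if (!edge_warned) {
        edge <- max(abs(psi[1, ]), abs(psi[n, ]))
        if (edge > 1e-6) {
          warning("wavefunction amplitude at the grid edge exceeds 1e-6 (",
                  format(edge, digits = 3),
                  "); results beyond this time are unreliable")
          edge_warned <- TRUE
        }
      }
      times <- c(times, tnow)
      snapshots[[length(snapshots) + 1L]] <- grid_wavefunction(x, psi, tnow)
    }
  }
  structure(list(times = times, snapshots = snapshots, x = x, dx = dx),
            class = "grid_wf_series")
}

#' @export
print.grid_wf_series <- function(x, ...) {
  cat(sprintf("<grid_wf_series> %d snapshots, t in [%.4g, %.4g] a.u.\n",
              length(x$snapshots), min(x$times), max(x$times)))
  invisible(x)
}

## adiabatic transformation matrices W(x_k) with sign continuity along x
.grid_adiabatic_frames <- function(model, x) {
  ns <- model$n_states
  Wlist <- array(0, c(ns, ns, length(x)))
  Elist <- matrix(0, length(x), ns)
  Wprev <- NULL
  for (k in seq_along(x)) {
    ap <- adiabatize(model, R = x[k])
    W <- ap$W
    if (!is.null(Wprev)) {
      ov <- crossprod(W, Wprev)
      for (c0 in seq_len(ns)) if (ov[c0, c0] < 0) W[, c0] <- -W[, c0]
    }
    Wlist[, , k] <- W
    Elist[k, ] <- ap$energies
    Wprev <- W
  }
  list(W = Wlist, E = Elist)
}

#' Populations, overlaps and coherences of a quantum propagation
#'
#' For each stored snapshot, returns diabatic and adiabatic populations, the
#' full adiabatic density matrix elements
#' \eqn{\rho_{ij}(t) = \int \tilde\chi_i(x,t)\,\tilde\chi_j^*(x,t)\,dx}
#' (equivalently \eqn{c_i c_j^* S_{ij}^*} with renormalized nuclear overlaps),
#' the renormalized overlap moduli \eqn{|S_{ij}|} (defined as 0 when either
#' population vanishes), total energy, norm, and any model-operator
#' expectation values \eqn{\langle O\rangle(t) = \int \psi^\dagger O(x) \psi\,
#' dx}.
#'
#' @param series a `grid_wf_series` from [split_operator_propagate()]
#' @param model the [diabatic_model()] used for the propagation
#' @return data frame with one row per stored time
#' @export
grid_observables <- function(series, model) {
  ns <- model$n_states
  x <- series$x; dx <- series$dx; n <- length(x)
  fr <- .grid_adiabatic_frames(model, x)
  mu <- model$masses[1]
  kvec <- 2 * pi / (n * dx) * c(0:(n %/% 2 - 1), -(n %/% 2):-1)
  rows <- lapply(series$snapshots, function(wf) {
    psi <- wf$psi
    pop_d <- colSums(abs(psi)^2) * dx
    ## pointwise adiabatic projection psi_ad = W(x)^T psi(x)
    psi_ad <- matrix(0i, n, ns)
    for (i in seq_len(ns)) {
      acc <- 0i
      for (j in seq_len(ns)) acc <- acc + fr$W[j, i, ] * psi[, j]
      psi_ad[, i] <- acc
    }
    rho <- crossprod(Conj(psi_ad), psi_ad) * dx   # rho[j,i] = int chi_i chi_j*
    rho <- t(rho)
    pop_a <- Re(diag(rho))
    ## renormalized nuclear overlap moduli
    Smod <- matrix(0, ns, ns)
    for (i in seq_len(ns)) for (j in seq_len(ns)) {
      if (pop_a[i] > 1e-300 && pop_a[j] > 1e-300) {
        Smod[i, j] <- Mod(rho[i, j]) / sqrt(pop_a[i] * pop_a[j])
      }
    }
    ## energy: kinetic via FFT + potential via pointwise matrices
    ekin <- 0
    for (j in seq_len(ns)) {
      ft <- stats::fft(psi[, j]) / n
      ekin <- ekin + sum(kvec^2 / (2 * mu) * abs(ft)^2) * n * dx
    }
    epot <- 0
    for (k in seq_len(n)) {
      V <- fr$W[, , k] %*% (fr$E[k, ] * t(fr$W[, , k]))
      epot <- epot + Re(crossprod(Conj(psi[k, ]), V %*% psi[k, ])) * dx
    }
    out <- c(time = wf$time, norm = sum(pop_d),
             stats::setNames(pop_d, paste0("pop_d", seq_len(ns))),
             stats::setNames(pop_a, paste0("pop_a", seq_len(ns))),
             energy = ekin + epot)
    for (i in seq_len(ns - 1)) for (j in (i + 1):ns) {
      out[paste0("re_rho", i, j)] <- Re(rho[i, j])
      out[paste0("im_rho", i, j)] <- Im(rho[i, j])
      out[paste0("s_abs", i, j)] <- Smod[i, j]
    }
    if (!is.null(model$operators)) {
      for (nm in names(model$operators)) {
        op <- model$operators[[nm]]
        acc <- 0
        for (k in seq_len(n)) {
          O <- op(x[k])
          acc <- acc + Re(crossprod(Conj(psi[k, ]), O %*% psi[k, ])) * dx
        }
        out[paste0("obs_", nm)] <- acc
      }
    }
    out
  })
  as.data.frame(do.call(rbind, rows))
}
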