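#' Integrator configuration for trajectory propagation
#'
#' @param dt nuclear time step, atomic units (use [fs_to_au()] for fs)
#' @param n_steps number of nuclear steps
#' @param n_substeps electronic substeps per nuclear step (default 51)
#' @param hop_scheme `"density_flux"` (default): hop probabilities from the
#'   flux of the active-state density between substeps; `"fssh"`: classic
#'   fewest-switches probabilities from the finite-difference time-derivative
#'   coupling (cross-check alternative)
#' @param record_every store every n-th nuclear step (initial and final
#'   states always stored)
#' @return object of class `integrator_config`
#' @export
integrator_config <- function(dt, n_steps, n_substeps = 51L,
                              hop_scheme = c("density_flux", "fssh"),
                              record_every = 1L) {
  stopifnot(dt > 0, n_steps >= 1, n_substeps >= 2)
  structure(list(dt = dt, n_steps = as.integer(n_steps),
                 n_substeps = as.integer(n_substeps),
                 hop_scheme = match.arg(hop_scheme),
                 record_every = as.integer(record_every)),
            class = "integrator_config")
}

#' One Velocity-Verlet nuclear step
#'
#' Standard Velocity-Verlet on the active surface: positions advance with the
#' step-start force, velocities with the mean of the step-start and step-end
#' forces.  The midpoint velocity (after the first half-kick) is exposed as
#' the reference for the auxiliary forces.
#'
#' @param R,v positions and velocities (atomic units)
#' @param masses per-dof masses (m_e)
#' @param force force at the current position (hartree/bohr)
#' @param force_fn function of position returning the force at the end of
#'   the step
#' @param dt nuclear time step (a.u.)
#' @return list with `R`, `v`, `v_half` (midpoint velocity), `force` (at the
#'   new position)
#' @export
nuclear_step <- function(R, v, masses, force, force_fn, dt) {
  if (any(!is.finite(force))) stop("non-finite force")
  v_half <- v + 0.5 * dt * force / masses
  R_new <- R + dt * v_half
  F_new <- force_fn(R_new)
  if (any(!is.finite(F_new))) stop("non-finite force")
  v_new <- v_half + 0.5 * dt * F_new / masses
  list(R = R_new, v = v_new, v_half = v_half, force = F_new)
}

#' State overlap matrix and finite-difference nonadiabatic coupling
#'
#' Enforces eigenvector sign continuity (columns of `W_now` are flipped when
#' their overlap with the previous step is negative), then returns
#' \eqn{S_{ij} = \langle \Psi_i(t) | \Psi_j(t - \Delta t)\rangle} (column dot
#' products) and the finite-difference time-derivative coupling
#' \eqn{K_{ij} = (\delta_{ij} - S_{ij}) / \Delta t}.
#'
#' @param W_prev,W_now orthogonal eigenvector matrices at the previous and
#'   current geometry
#' @param dt time separating the two frames (a.u.)
#' @return list with `S`, `K`, and the sign-fixed `W_now`
#' @export
electronic_overlap_and_nac <- function(W_prev, W_now, dt) {
  if (!all(dim(W_prev) == dim(W_now))) stop("dimension mismatch")
  S <- t(W_now) %*% W_prev
  for (k in seq_len(ncol(W_now))) {
    if (S[k, k] < 0) {
      W_now[, k] <- -W_now[, k]
      S[k, ] <- -S[k, ]
    }
  }
  K <- (diag(nrow(S)) - S) / dt
  list(S = S, K = K, W_now = W_now)
}

#' Local diabatization matrix from a state overlap matrix
#'
#' The unitary matrix closest to `S` in the Frobenius sense (polar factor,
#' computed by SVD; equivalently symmetric orthogonalization), with columns
#' flipped so the diagonal is non-negative.  Applied cumulatively,
#' \eqn{U(0, t_0 + \Delta t) = U(t_0, t_0 + \Delta t)\,U(0, t_0)}, it defines
#' the transported (locally diabatic) electronic basis in which the
#' coefficients are propagated.
#'
#' @param S square near-orthogonal overlap matrix
#' @return orthogonal matrix `U`
#' @export
local_diabatization_matrix <- function(S) {
  S <- as.matrix(S)
  sv <- svd(S)
  if (min(sv$d) < 1e-12) stop("local diabatization: singular overlap matrix")
  if (max(abs(crossprod(S) - diag(nrow(S)))) > 0.5) {
    stop("overlap matrix too far from orthogonal")
  }
  U <- sv$u %*% t(sv$v)
  for (k in seq_len(ncol(U))) if (U[k, k] < 0) U[, k] <- -U[, k]
  U
}

#' Propagate electronic coefficients across one nuclear step
#'
#' Integrates \eqn{i\,\dot{\tilde c} = (\tilde V - i\tilde K)\,\tilde c} in
#' the local diabatic basis with the Runge-Kutta-4 method over `n_substeps`
#' equal substeps, interpolating the diabatized potential and residual
#' coupling linearly between the step endpoints.  The norm is restored after
#' every substep.
#'
#' @param c0 complex coefficient vector at the step start (local diabatic
#'   basis)
#' @param V0,V1 diabatized potential matrices at the step endpoints
#' @param K0,K1 diabatized residual coupling matrices at the step endpoints
#' @param dt nuclear step (a.u.)
#' @param n_substeps number of RK4 substeps
#' @return complex coefficient vector at the step end
#' @export
electronic_substep_propagation <- function(c0, V0, V1, K0 = NULL, K1 = NULL,
                                           dt, n_substeps = 51L) {
  ns <- length(c0)
  if (is.null(K0)) K0 <- matrix(0, ns, ns)
  if (is.null(K1)) K1 <- matrix(0, ns, ns)
  if (any(!is.finite(V0)) || any(!is.finite(V1))) stop("non-finite interpolant")
  H0 <- V0 - 1i * K0
  H1 <- V1 - 1i * K1
  ct <- as.complex(c0)
  dsub <- dt / n_substeps
  for (s in seq_len(n_substeps)) {
    s0 <- (s - 1) / n_substeps
    s1 <- s / n_substeps
    sm <- (s0 + s1) / 2
    Ha <- H0 + s0 * (H1 - H0)
    Hm <- H0 + sm * (H1 - H0)
    Hb <- H0 + s1 * (H1 - H0)
    k1 <- -1i * (Ha %*% ct)
    k2 <- -1i * (Hm %*% (ct + 0.5 * dsub * k1))
    k3 <- -1i * (Hm %*% (ct + 0.5 * dsub * k2))
    k4 <- -1i * (Hb %*% (ct + dsub * k3))
    ct <- ct + dsub / 6 * (k1 + 2 * k2 + 2 * k3 + k4)
    ct <- ct / sqrt(sum(Mod(ct)^2))
  }
  drop(ct)
}

#' Density-flux hopping probabilities
#'
#' Probability of hopping from the active state to each other state within
#' one electronic substep, from the change of the density diagonals:
#' \deqn{P_{a\to k} = \frac{\max(0, \rho_{aa}(t') - \rho_{aa}(t' + \delta
#'   t))}{\rho_{aa}(t')} \cdot \frac{\max(0, \Delta\rho_{kk})}{\sum_{l \ne a}
#'   \max(0, \Delta\rho_{ll})}}
#' Zero everywhere when the active population did not decrease; the
#' probabilities sum to at most 1.  A vanishing active population yields all
#' zeros.
#'
#' @param rho_before,rho_after density diagonals before/after the substep
#' @param active active state index
#' @return per-state probability vector (entry `active` is 0)
#' @export
hop_probabilities <- function(rho_before, rho_after, active) {
  ns <- length(rho_before)
  g <- numeric(ns)
  if (rho_before[active] <= 0) return(g)
  loss <- max(0, rho_before[active] - rho_after[active]) / rho_before[active]
  if (loss == 0) return(g)
  gains <- pmax(0, rho_after - rho_before)
  gains[active] <- 0
  tot <- sum(gains)
  if (tot == 0) return(g)
  loss * gains / tot
}

#' Hop selection, frustration test and rescale factor
#'
#' Selects the hop target by the cumulative-interval rule on `probabilities`
#' using the uniform draw `r`; a selected hop is carried out only when the
#' kinetic energy can cover the potential-energy gap
#' (\eqn{V_{aa} + T \ge V_{kk}}), otherwise it is frustrated and the
#' velocities are left untouched.
#'
#' @param active current active state
#' @param probabilities from [hop_probabilities()]
#' @param r uniform random draw in `[0, 1]`
#' @param energies adiabatic energies (hartree)
#' @param T available kinetic energy (hartree)
#' @return list with `active` (possibly updated), `target` (selected state or
#'   `NA`), `hopped`, `frustrated`
#' @export
attempt_hop <- function(active, probabilities, r, energies, T) {
  cum <- 0
  target <- NA_integer_
  for (k in seq_along(probabilities)) {
    if (k == active) next
    cum <- cum + probabilities[k]
    if (r <= cum) { target <- k; break }
  }
  if (is.na(target)) {
    return(list(active = active, target = NA_integer_, hopped = FALSE,
                frustrated = FALSE))
  }
  if (energies[active] + T >= energies[target]) {
    list(active = target, target = target, hopped = TRUE, frustrated = FALSE)
  } else {
    list(active = active, target = target, hopped = FALSE, frustrated = TRUE)
  }
}

#' Isotropic velocity rescale factor after a surface hop
#'
#' \eqn{\sqrt{1 - \Delta E / T}} with \eqn{\Delta E} the total-energy jump of
#' the step (end-active energy plus end kinetic energy minus start-active
#' energy plus start kinetic energy).
#'
#' @param dE total-energy difference (hartree)
#' @param T kinetic energy before rescaling (hartree)
#' @return scalar factor
#' @export
hop_rescale_factor <- function(dE, T) {
  rad <- 1 - dE / T
  if (rad < 0) stop("negative radicand: hop should have been frustrated")
  sqrt(rad)
}

## resolve decoherence parameters against a model (fill mu/omega/n_d)
.deco_resolve <- function(deco, model) {
  if (deco$variant %in% c("fm", "fmi")) {
    if (is.null(deco$mu)) deco$mu <- model$masses[1]
    if (model$n_dof != 1L) stop("FM decoherence is one-dimensional")
    if (is.null(deco$sigma)) stop("FM decoherence requires sigma")
  }
  if (deco$variant %in% c("pfm", "pfmi")) {
    if (is.null(deco$omega) || is.null(deco$n_d)) {
      if (is.null(model$normal_modes)) {
        stop("PFM decoherence requires omega and n_d (or model normal modes)")
      }
      ws <- width_parameters(model$normal_modes)
      if (is.null(deco$omega)) deco$omega <- ws$omega
      if (is.null(deco$n_d)) deco$n_d <- ws$n_d
    }
  }
  deco
}

.variant_code <- c(nd = 0L, edc = 1L, fm = 2L, fmi = 3L, pfm = 4L, pfmi = 5L)

#' Propagate a single surface-hopping trajectory
#'
#' Runs one fewest-switches trajectory from the given phase-space point and
#' initial electronic coefficients.  Diabatic-basis coefficients are
#' transformed to the adiabatic basis with the eigenvector matrix at the
#' initial geometry; the initial active surface is drawn with probabilities
#' \eqn{|c_j(0)|^2}.  The random-number generator is (re)seeded per
#' trajectory, making records exactly reproducible.
#'
#' @param model a [diabatic_model()]
#' @param R0,p0 initial position and momentum vectors (atomic units)
#' @param coefficients initial complex electronic coefficients
#' @param basis basis of `coefficients`: `"diabatic"` (default) or
#'   `"adiabatic"`
#' @param config an [integrator_config()]
#' @param deco a [decoherence_config()]
#' @param seed integer seed for this trajectory
#' @param engine `"cpp"` (compiled, default) or `"r"` (reference
#'   implementation assembled from the exported step operations)
#' @return object of class `tsh_trajectory`: list with `times`, `positions`,
#'   `velocities`, `active`, `coefficients` (adiabatic, rows = times),
#'   `energy` (total), `p_aux`, `hops` (data frame), `failed`, `seed`
#' @export
run_trajectory <- function(model, R0, p0, coefficients,
                           basis = c("diabatic", "adiabatic"),
                           config, deco = decoherence_config("nd"),
                           seed = 1L, engine = c("cpp", "r")) {
  basis <- match.arg(basis)
  engine <- match.arg(engine)
  deco <- .deco_resolve(deco, model)
  R0 <- as.numeric(R0)
  v0 <- as.numeric(p0) / model$masses
  ap <- adiabatize(model, R = R0)
  cvec <- as.complex(coefficients)
  cvec <- cvec / sqrt(sum(Mod(cvec)^2))
  cad <- if (basis == "diabatic") drop(t(ap$W) %*% cvec) else cvec
  cad <- cad / sqrt(sum(Mod(cad)^2))
  set.seed(seed)
  r <- stats::runif(1)
  active0 <- which(r <= cumsum(Mod(cad)^2))[1]
  if (is.na(active0)) active0 <- length(cad)  # cumulative rounding guard
  pars <- list(dt = config$dt, n_steps = config$n_steps,
               n_substeps = config$n_substeps,
               hop_scheme = if (config$hop_scheme == "density_flux") 0L else 1L,
               record_every = config$record_every,
               variant = .variant_code[[deco$variant]],
               C = deco$C %||% 0.1, sigma = deco$sigma %||% 1,
               mu = deco$mu %||% 1, omega = deco$omega %||% 1,
               n_d = deco$n_d %||% 1L, eta = deco$eta, kappa = deco$kappa)
  raw <- if (engine == "cpp") {
    .tsh_trajectory_cpp(model, R0, v0, Re(cad), Im(cad), active0, pars)
  } else {
    .tsh_trajectory_r(model, R0, v0, cad, active0, pars)
  }
  if (!is.null(raw$coefficients_re)) {
    raw$coefficients <- raw$coefficients_re + 1i * raw$coefficients_im
  }
  hops <- as.data.frame(raw$hops)
  names(hops) <- c("time", "from", "to", "frustrated")
  structure(list(times = as.numeric(raw$times),
                 positions = raw$positions, velocities = raw$velocities,
                 active = as.integer(raw$active),
                 coefficients = raw$coefficients,
                 energy = as.numeric(raw$energy), p_aux = raw$p_aux,
                 hops = hops, failed = isTRUE(raw$failed),
                 fail_reason = raw$fail_reason, seed = seed,
                 deco = deco$variant),
            class = "tsh_trajectory")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' @export
print.tsh_trajectory <- function(x, ...) {
  cat(sprintf("<tsh_trajectory> %d recorded steps, %.4g a.u. (%.3f fs), deco = %s\n",
              length(x$times) - 1L, max(x$times), au_to_fs(max(x$times)),
              x$deco))
  cat(sprintf("  hops: %d executed, %d frustrated; energy drift %.3g hartree%s\n",
              sum(x$hops$frustrated == 0), sum(x$hops$frustrated == 1),
              max(abs(x$energy - x$energy[1])),
              if (x$failed) paste0("; FAILED: ", x$fail_reason) else ""))
  invisible(x)
}

## polar factor without the diagonal-sign convention (used to
## re-orthogonalize interpolated cumulative diabatization matrices)
.polar <- function(S) {
  sv <- svd(S)
  if (min(sv$d) < 1e-12) stop("singular interpolated diabatization matrix")
  sv$u %*% t(sv$v)
}

## ---- R reference engine ---------------------------------------------------
## Assembled from the exported step operations; mirrors the compiled engine's
## draw schedule (one uniform per substep) so that results agree numerically.
.tsh_trajectory_r <- function(model, R0, v0, c0, active0, pars) {
  ns <- model$n_states
  m <- model$masses; sqm <- sqrt(m)
  dt <- pars$dt; n_sub <- pars$n_substeps; dsub <- dt / n_sub
  eta <- pars$eta; kappa <- pars$kappa
  variant <- pars$variant
  deco <- switch(variant + 1L,
    decoherence_config("nd"),
    decoherence_config("edc", C = pars$C),
    decoherence_config("fm", sigma = pars$sigma, mu = pars$mu, eta = eta,
                       kappa = kappa),
    decoherence_config("fmi", sigma = pars$sigma, mu = pars$mu, eta = eta,
                       kappa = kappa),
    decoherence_config("pfm", omega = pars$omega, n_d = pars$n_d, eta = eta,
                       kappa = kappa),
    decoherence_config("pfmi", omega = pars$omega, n_d = pars$n_d, eta = eta,
                       kappa = kappa))
  kin <- function(v) 0.5 * sum(m * v^2)

  a <- active0
  R <- R0; v <- v0
  ap <- adiabatize(model, R = R)
  E_old <- ap$energies; W_old <- ap$W
  cad <- c0 / sqrt(sum(Mod(c0)^2))
  ctil <- cad
  U_cum <- diag(ns)
  Vt0 <- diag(E_old); Kt0 <- matrix(0, ns, ns); Kad0 <- matrix(0, ns, ns)
  Fc <- -adiabatic_gradient(model, R, a)
  T0 <- kin(v)
  pa0 <- if (model$n_dof == 1L) m[1] * v[1] else sqrt(sum((sqm * v)^2))
  slavef <- function(eia, T) {
    if (T <= 0) return(if (eia <= 0) 1 else 0)
    sqrt(max(0, 1 - eia / T))
  }
  paux <- vapply(seq_len(ns), function(j) {
    if (Mod(cad[j])^2 >= eta || j == a) pa0
    else pa0 * slavef(E_old[j] - E_old[a], T0)
  }, numeric(1))
  faux <- numeric(ns)

  rec <- list(times = 0, R = list(R), v = list(v), a = a,
              c = list(cad), E = E_old[a] + kin(v), paux = list(paux))
  hops <- matrix(numeric(0), 0, 4)

  for (step in seq_len(pars$n_steps)) {
    a_start <- a
    pop_old <- Mod(cad)^2
    Tstart <- kin(v)
    v_half <- v + 0.5 * dt * Fc / m
    R_new <- R + dt * v_half
    ap <- adiabatize(model, R = R_new)
    ov <- electronic_overlap_and_nac(W_old, ap$W, dt)
    W_new <- ov$W_now; S <- ov$S
    E_new <- ap$energies
    vref <- if (model$n_dof == 1L) v_half[1] else sqrt(sum((sqm * v_half)^2))
    faux <- tvp_force(E_old, E_new, vref, dt, kappa)
    U_step <- local_diabatization_matrix(S)
    U_new <- U_step %*% U_cum
    Vt1 <- t(U_new) %*% diag(E_new) %*% U_new
    Kt1 <- (diag(ns) - t(U_new) %*% S %*% U_cum) / dt
    Kad1 <- ov$K
    need_polar <- max(abs(U_step - diag(ns))) > 0.02
    Tmid <- kin(v_half)
    kdec <- decoherence_rates(deco, a, paux, faux, E_old, Tstart)
    ## global-phase gauge: subtract the step-mean diagonal energy
    eshift <- (sum(diag(Vt0)) + sum(diag(Vt1))) / (2 * ns)
    H0 <- Vt0 - eshift * diag(ns) - 1i * Kt0
    H1 <- Vt1 - eshift * diag(ns) - 1i * Kt1
    rho_prev <- Mod(cad)^2
    for (ssub in seq_len(n_sub)) {
      s0 <- (ssub - 1) / n_sub; s1 <- ssub / n_sub; sm <- (s0 + s1) / 2
      Ha <- H0 + s0 * (H1 - H0); Hm <- H0 + sm * (H1 - H0)
      Hb <- H0 + s1 * (H1 - H0)
      k1 <- -1i * (Ha %*% ctil)
      k2 <- -1i * (Hm %*% (ctil + 0.5 * dsub * k1))
      k3 <- -1i * (Hm %*% (ctil + 0.5 * dsub * k2))
      k4 <- -1i * (Hb %*% (ctil + dsub * k3))
      ctil <- drop(ctil + dsub / 6 * (k1 + 2 * k2 + 2 * k3 + k4))
      ctil <- ctil / sqrt(sum(Mod(ctil)^2))
      U_s <- U_cum + s1 * (U_new - U_cum)
      if (need_polar) U_s <- .polar(U_s)
      cad <- drop(U_s %*% ctil)
      cad <- cad / sqrt(sum(Mod(cad)^2))
      rho_now <- Mod(cad)^2
      g <- if (pars$hop_scheme == 0L) {
        hop_probabilities(rho_prev, rho_now, a)
      } else {
        Kad <- Kad0 + s1 * (Kad1 - Kad0)
        gk <- numeric(ns)
        if (rho_now[a] > 0) {
          for (k in seq_len(ns)) {
            if (k == a) next
            flux <- 2 * Re(Kad[a, k] * cad[k] * Conj(cad[a]))
            gk[k] <- max(0, dsub * flux / rho_now[a])
          }
        }
        gk
      }
      r <- stats::runif(1)
      E_s <- E_old + s1 * (E_new - E_old)
      ah <- attempt_hop(a, g, r, E_s, Tmid)
      if (!is.na(ah$target)) {
        hops <- rbind(hops, c((step - 1) * dt + s1 * dt, a, ah$target,
                              as.numeric(ah$frustrated)))
        if (ah$hopped) {
          a <- ah$active
          kdec <- decoherence_rates(deco, a, paux, faux, E_old, Tstart)
        }
      }
      if (variant != 0L) {
        cad <- apply_decoherence(cad, kdec, a, dsub)
        ctil <- drop(t(U_s) %*% cad)
        ctil <- ctil / sqrt(sum(Mod(ctil)^2))
      }
      rho_prev <- Mod(cad)^2
    }
    cad <- drop(U_new %*% ctil)
    cad <- cad / sqrt(sum(Mod(cad)^2))
    F_new <- -adiabatic_gradient(model, R_new, a)
    v_new <- v_half + 0.5 * dt * F_new / m
    hop_factor <- 1
    if (a != a_start) {
      T_end <- kin(v_new)
      dE <- E_new[a] + T_end - (E_old[a_start] + Tstart)
      rad <- if (T_end > 0) 1 - dE / T_end else -1
      if (rad < 0) {
        a <- a_start
        F_new <- -adiabatic_gradient(model, R_new, a)
        v_new <- v_half + 0.5 * dt * F_new / m
        hops[nrow(hops), 4] <- 1
      } else {
        hop_factor <- sqrt(rad)
        v_new <- v_new * hop_factor
      }
    }
    pop_new <- Mod(cad)^2
    T_post <- kin(v_new)
    paux <- aux_momentum_update(paux, faux, pop_old, pop_new, E_new,
                                T_post, a, a_start, hop_factor, dt,
                                eta, variant %in% c(3L, 5L))
    for (i in seq_len(ns)) {
      if (i == a) next
      if (pop_old[i] >= eta && pop_new[i] < eta && pop_new[i] > 0) {
        ca2 <- Mod(cad[a])^2
        if (ca2 > 0) {
          cad[a] <- cad[a] * sqrt(1 + pop_new[i] / ca2)
          cad[i] <- 0i
        }
      }
    }
    cad <- cad / sqrt(sum(Mod(cad)^2))
    ctil <- drop(t(U_new) %*% cad)
    ctil <- ctil / sqrt(sum(Mod(ctil)^2))

    R <- R_new; v <- v_new; Fc <- F_new
    E_old <- E_new; W_old <- W_new; U_cum <- U_new
    Vt0 <- Vt1; Kt0 <- Kt1; Kad0 <- Kad1
    if (step %% pars$record_every == 0 || step == pars$n_steps) {
      rec$times <- c(rec$times, step * dt)
      rec$R <- c(rec$R, list(R)); rec$v <- c(rec$v, list(v))
      rec$a <- c(rec$a, a); rec$c <- c(rec$c, list(cad))
      rec$E <- c(rec$E, E_old[a] + kin(v))
      rec$paux <- c(rec$paux, list(paux))
    }
  }
  list(times = rec$times, positions = do.call(rbind, rec$R),
       velocities = do.call(rbind, rec$v), active = rec$a,
       coefficients = do.call(rbind, rec$c), energy = rec$E,
       p_aux = do.call(rbind, rec$paux), hops = hops, failed = FALSE,
       fail_reason = "")
}
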