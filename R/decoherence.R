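#' Decoherence configuration
#'
#' Selects the decoherence variant applied during trajectory propagation and
#' validates its parameters:
#' \describe{
#'   \item{`"nd"`}{no decoherence correction (bare fewest-switches).}
#'   \item{`"edc"`}{energy-based decoherence correction,
#'     \eqn{k = |E_{ia}|\,T/(T + C)}; needs `C` (hartree, default 0.1).}
#'   \item{`"fm"`, `"fmi"`}{forces-and-momenta rate for one-dimensional
#'     systems; needs the wave-packet width `sigma` (bohr) and reduced mass
#'     `mu` (m_e).  `"fmi"` additionally injects rescaled active-potential
#'     auxiliary momentum whenever an inactive population grows.}
#'   \item{`"pfm"`, `"pfmi"`}{projected-forces-and-momenta rate for
#'     multidimensional systems; needs the common frequency `omega` (hartree)
#'     and the number of nonzero-frequency modes `n_d`.}
#' }
#' `eta` is the inactive-potential population threshold below which a state is
#' regarded as carrying no wave packet (default `1e-4`); `kappa` is the
#' velocity threshold below which auxiliary forces are zeroed (default
#' `1e-9`).
#'
#' @param variant one of `"nd"`, `"edc"`, `"fm"`, `"fmi"`, `"pfm"`, `"pfmi"`
#' @param C,sigma,mu,omega,n_d variant parameters, see Description
#' @param eta,kappa thresholds, see Description
#' @return object of class `decoherence_config`
#' @export
decoherence_config <- function(variant = c("nd", "edc", "fm", "fmi",
                                           "pfm", "pfmi"),
                               C = 0.1, sigma = NULL, mu = NULL,
                               omega = NULL, n_d = NULL,
                               eta = 1e-4, kappa = 1e-9) {
  variant <- match.arg(variant)
  chk <- function(x, nm) {
    if (is.null(x) || !is.finite(x) || x <= 0) {
      stop("decoherence variant '", variant, "' requires positive ", nm)
    }
    x
  }
  if (variant == "edc") chk(C, "C")
  if (variant %in% c("fm", "fmi")) { chk(sigma, "sigma"); chk(mu, "mu") }
  if (variant %in% c("pfm", "pfmi")) { chk(omega, "omega"); chk(n_d, "n_d") }
  stopifnot(eta > 0, kappa > 0)
  structure(list(variant = variant, C = C, sigma = sigma, mu = mu,
                 omega = omega, n_d = n_d, eta = eta, kappa = kappa,
                 injection = variant %in% c("fmi", "pfmi")),
            class = "decoherence_config")
}

#' Energy-based decoherence rate (EDC)
#'
#' \eqn{k = |E_{ij}| \cdot T/(T + C)}: vanishes for particles at rest and
#' approaches the potential-energy difference for \eqn{T \gg C}.
#'
#' @param E_ij_abs absolute potential-energy difference (hartree)
#' @param T kinetic energy (hartree), `>= 0`
#' @param C range parameter (hartree), default 0.1
#' @return decay rate, 1/a.u. of time
#' @export
edc_rate <- function(E_ij_abs, T, C = 0.1) {
  stopifnot(all(T >= 0), C > 0)
  abs(E_ij_abs) * T / (T + C)
}

#' Forces-and-momenta decoherence rate, one-dimensional form
#'
#' First-order decay rate of the frozen-Gaussian nuclear overlap between two
#' surfaces of a diatomic with reduced mass \eqn{\mu}, bond-coordinate
#' momentum and force differences \eqn{p_{ij}, f_{ij}}, and wave-packet width
#' \eqn{\sigma}:
#' \deqn{k = \frac{\sigma^2}{2}\left(p_{ij} f_{ij} + |p_{ij}|
#'   \sqrt{f_{ij}^2 + \frac{1}{\mu^2 \sigma^6}}\right) \ge 0.}
#'
#' @param p_ij momentum difference (a.u.)
#' @param f_ij force difference (hartree/bohr)
#' @param sigma wave-packet width (bohr)
#' @param mu reduced mass (m_e)
#' @return non-negative decay rate
#' @export
fm_rate_1d <- function(p_ij, f_ij, sigma, mu) {
  stopifnot(sigma > 0, mu > 0)
  sigma^2 / 2 * (p_ij * f_ij +
                   abs(p_ij) * sqrt(f_ij^2 + 1 / (mu^2 * sigma^6)))
}

#' Projected-forces-and-momenta decoherence rate (PFM)
#'
#' Multidimensional decoherence rate in terms of the moduli of the
#' mass-weighted trajectory-velocity-projected momentum and force differences,
#' a common frequency \eqn{\omega} and the number of vibrational modes
#' \eqn{N_D}:
#' \deqn{k = \frac{\pi^2}{8\omega}|P^v_{ij}||F^v_{ij}|
#'   + |P^v_{ij}|\sqrt{\frac{\pi^2 N_D \omega}{8}} \ge 0.}
#'
#' @param P_ij_abs modulus of the TVP momentum difference (a.u.)
#' @param F_ij_abs modulus of the TVP force difference (a.u.)
#' @param omega common frequency (hartree)
#' @param n_d number of nonzero-frequency modes
#' @return non-negative decay rate
#' @export
pfm_rate <- function(P_ij_abs, F_ij_abs, omega, n_d) {
  stopifnot(omega > 0, n_d >= 1)
  pi^2 / (8 * omega) * abs(P_ij_abs) * abs(F_ij_abs) +
    abs(P_ij_abs) * sqrt(pi^2 * n_d * omega / 8)
}

#' Forces-and-momenta rate in normal-mode coordinates
#'
#' The mode-resolved rate
#' \deqn{k = \sum_\alpha \frac{1}{4\omega_\alpha}\left(\dot q_\alpha \ddot
#'   q_\alpha + |\dot q_\alpha|\sqrt{\ddot q_\alpha^2 +
#'   8\omega_\alpha^3}\right)}
#' over mass-weighted normal-mode velocity and acceleration differences.  It
#' is retained as the reference form: the one-dimensional rate
#' [fm_rate_1d()] is its single-mode special case under
#' \eqn{\dot q = \mu^{-1/2} p}, \eqn{\ddot q = \mu^{-1/2} f},
#' \eqn{\omega = 1/(2\mu\sigma^2)}, and the PFM rate derives from its common-
#' frequency upper bound.
#'
#' @param qdot_ij normal-mode velocity differences (one per mode)
#' @param qddot_ij normal-mode acceleration differences (one per mode)
#' @param omega mode frequencies (positive, one per mode)
#' @return non-negative decay rate
#' @export
fm_rate_normal_modes <- function(qdot_ij, qddot_ij, omega) {
  stopifnot(length(qdot_ij) == length(qddot_ij),
            length(omega) == length(qdot_ij), all(omega > 0))
  sum(1 / (4 * omega) *
        (qdot_ij * qddot_ij +
           abs(qdot_ij) * sqrt(qddot_ij^2 + 8 * omega^3)))
}

#' Common-frequency upper bound to the normal-mode FM rate
#'
#' \eqn{\frac{1}{2\omega}|\dot q||\ddot q| + |\dot q|\sqrt{N_D\,\omega/2}}
#' with \eqn{|\cdot|} Euclidean norms over modes; always an upper bound to
#' [fm_rate_normal_modes()] when all mode frequencies equal `omega`.
#'
#' @inheritParams fm_rate_normal_modes
#' @param omega common frequency (scalar)
#' @return upper bound to the rate
#' @export
fm_rate_common_omega_bound <- function(qdot_ij, qddot_ij, omega) {
  nq <- sqrt(sum(qdot_ij^2)); na <- sqrt(sum(qddot_ij^2))
  nq * na / (2 * omega) + nq * sqrt(length(qdot_ij) * omega / 2)
}

#' Trajectory-velocity-projected auxiliary force
#'
#' Forward finite difference of a surface's potential energy along the
#' trajectory, divided by the reference velocity:
#' \eqn{F = -(E(t+\Delta t) - E(t))/(v\,\Delta t)} if \eqn{|v| \ge \kappa},
#' else 0.  The reference velocity is the mass-weighted speed at the step
#' midpoint in multidimensional dynamics, and the (signed) bond-length
#' velocity in one dimension.
#'
#' @param E_now,E_next potential energy at the start and end of the step
#'   (hartree); vectors are handled elementwise
#' @param v reference velocity (a.u.)
#' @param dt nuclear time step (a.u.)
#' @param kappa velocity threshold below which the force is zeroed
#' @return auxiliary force(s)
#' @export
tvp_force <- function(E_now, E_next, v, dt, kappa = 1e-9) {
  stopifnot(dt > 0)
  if (abs(v) < kappa) return(rep(0, length(E_now)))
  -(E_next - E_now) / (v * dt)
}

#' One nuclear-step update of the auxiliary momenta
#'
#' Implements the per-step bookkeeping of the per-state auxiliary momenta:
#' the active-potential momentum is propagated classically with the (new)
#' active auxiliary force and, on a surface hop, rescaled by the same
#' isotropic factor as the velocities; above-threshold inactive momenta are
#' propagated with their own auxiliary forces, optionally blending in
#' energy-rescaled active-potential momentum proportionally to any population
#' gain (momentum injection); subthreshold inactive momenta are slaved to the
#' energy-rescaled active value.  A population rising above the threshold
#' (birth) automatically switches from the slaved to the propagated branch at
#' the slaved value; all square roots are guarded by `max(0, .)`.
#'
#' @param p_aux numeric vector of auxiliary momenta at step start
#' @param aux_forces auxiliary forces \eqn{F_j^{aux}(t_0)} (from
#'   [tvp_force()])
#' @param pop_old,pop_new adiabatic populations at step start/end
#' @param energies_new adiabatic energies at step end (hartree)
#' @param T_new kinetic energy at step end, after any hop rescaling (hartree)
#' @param active_new,active_old active state at step end/start
#' @param hop_factor velocity rescale factor applied at this step's hop
#'   (`1` when no hop occurred)
#' @param dt nuclear step (a.u.)
#' @param eta population threshold
#' @param injection logical: apply active-momentum injection on population
#'   gain (the FMi/PFMi variants)
#' @return updated auxiliary momentum vector
#' @export
aux_momentum_update <- function(p_aux, aux_forces, pop_old, pop_new,
                                energies_new, T_new, active_new, active_old,
                                hop_factor = 1, dt, eta = 1e-4,
                                injection = FALSE) {
  ns <- length(p_aux)
  out <- p_aux
  ## active: continue from the previous active momentum (continuity across
  ## hops), propagate with the new active's force, rescale on hop
  pa <- p_aux[active_old] + aux_forces[active_new] * dt
  if (active_new != active_old) pa <- pa * hop_factor
  out[active_new] <- pa
  for (i in seq_len(ns)) {
    if (i == active_new) next
    eia <- energies_new[i] - energies_new[active_new]
    slave <- pa * sqrt(max(0, 1 - ifelse(T_new > 0, eia / T_new, Inf)))
    if (pop_old[i] >= eta && pop_new[i] >= eta) {
      pi_new <- p_aux[i] + aux_forces[i] * dt
      drho <- pop_new[i] - pop_old[i]
      if (injection && drho > 0) {
        frac <- drho / pop_new[i]
        pi_new <- pi_new * (1 - frac) + frac * slave
      }
      out[i] <- pi_new
    } else {
      out[i] <- slave
    }
  }
  out
}

#' Decoherence rates towards the active state
#'
#' Evaluates the per-state decay rate \eqn{k_{ia}} of every inactive state
#' for the configured variant, from step-start quantities.
#'
#' @param deco a [decoherence_config()]
#' @param active active state index
#' @param p_aux,aux_forces auxiliary momenta and forces (FM/PFM variants)
#' @param energies adiabatic energies (hartree; EDC and not otherwise needed)
#' @param T kinetic energy (hartree; EDC)
#' @return numeric vector of rates, entry `active` equal to 0
#' @export
decoherence_rates <- function(deco, active, p_aux = NULL, aux_forces = NULL,
                              energies = NULL, T = NULL) {
  ns <- length(if (!is.null(energies)) energies else p_aux)
  k <- numeric(ns)
  if (deco$variant == "nd") return(k)
  for (i in seq_len(ns)) {
    if (i == active) next
    k[i] <- switch(deco$variant,
      edc = edc_rate(abs(energies[i] - energies[active]), T, deco$C),
      fm = , fmi = fm_rate_1d(p_aux[i] - p_aux[active],
                              aux_forces[i] - aux_forces[active],
                              deco$sigma, deco$mu),
      pfm = , pfmi = pfm_rate(abs(p_aux[i] - p_aux[active]),
                              abs(aux_forces[i] - aux_forces[active]),
                              deco$omega, deco$n_d))
  }
  k
}

#' Apply the decoherence correction to electronic coefficients
#'
#' Damps every inactive coefficient with its first-order overlap decay,
#' \eqn{c_i \leftarrow c_i e^{-k_{ia}\,\delta t}}, and rescales the active
#' coefficient to restore unit norm.  If `pop_prev` is supplied, any inactive
#' population that crossed below the threshold `eta` during the step is
#' treated as fully decohered: its residual is moved into the active
#' coefficient and the inactive coefficient is zeroed.
#'
#' @param coefficients complex unit-norm coefficient vector
#' @param rates non-negative decay rates (entry `active` ignored)
#' @param active active state index
#' @param dt damping interval (a.u.)
#' @param eta population threshold for the collapse branch
#' @param pop_prev populations before the step, or `NULL` to skip the
#'   collapse branch
#' @return updated unit-norm coefficient vector
#' @export
apply_decoherence <- function(coefficients, rates, active, dt,
                              eta = 1e-4, pop_prev = NULL) {
  c0 <- as.complex(coefficients)
  ns <- length(c0)
  inact <- setdiff(seq_len(ns), active)
  if (any(rates[inact] > 0) && Mod(c0[active]) == 0) {
    stop("active coefficient is zero; decoherence rescaling is ill-posed")
  }
  c0[inact] <- c0[inact] * exp(-rates[inact] * dt)
  rest <- 1 - sum(abs(c0[inact])^2)
  c0[active] <- c0[active] / Mod(c0[active]) * sqrt(max(0, rest))
  if (!is.null(pop_prev)) {
    for (i in inact) {
      if (pop_prev[i] >= eta && Mod(c0[i])^2 < eta && Mod(c0[i])^2 > 0) {
        c0[active] <- c0[active] *
          sqrt(1 + Mod(c0[i])^2 / Mod(c0[active])^2)
        c0[i] <- 0i
      }
    }
  }
  c0 / sqrt(sum(Mod(c0)^2))
}
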