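#' Build a diabatic model from a preset name or a parameter table
#'
#' Presets shipped with the package:
#' \describe{
#'   \item{`"avoided_crossing_2s"`}{Two-state, one-dimensional avoided
#'     crossing: two exponentially repulsive diabats with different slopes and
#'     asymptotes and a constant coupling.  A Gaussian wave packet released on
#'     the upper diabat slides through the crossing and splits; the reduced
#'     mass is 2000 m_e.  This is the preset validated directly against the
#'     exact grid propagator.}
#'   \item{`"ibr_surrogate_3s"`}{Three-state, one-dimensional surrogate of a
#'     heavy diatomic interhalogen photodissociation (IBr-like): a deep bound
#'     Morse ground state, one quasi-bound and one repulsive-then-flat excited
#'     diabat that cross each other away from the Franck-Condon point, and
#'     constant diabatic couplings (the nonadiabatic coupling of the emulated
#'     model is constant).  Reduced mass 89380 m_e and ground-state harmonic
#'     frequency 1.173e-3 hartree are chosen so that the ground-state
#'     bond-length standard deviation is 6.906e-2 bohr.  The numeric
#'     parameters are repo-defined (the original diabatic parameters are not
#'     published with the emulated curves); only the qualitative structure --
#'     promotion, excited-excited crossing, two dissociation channels -- is
#'     reproduced.}
#'   \item{`"tully3_sloped"`}{Two sloped linear diabats crossing once with a
#'     Gaussian coupling centred at the crossing; a molecular-Tully-III-style
#'     sloped-crossing situation.}
#'   \item{`"lvc_nd"`}{Two-state, three-mode linear vibronic coupling model in
#'     dimensionless normal-mode coordinates (unit masses), with one coupling
#'     and two tuning modes; the multidimensional test bed for the PFM rate.}
#' }
#'
#' Alternatively pass a parameter table: a list with `n_states`, `masses`, and
#' `terms` (or `lvc`), forwarded to [diabatic_model()].
#'
#' @param preset preset name, or a parameter-table list
#' @param ... overrides merged over the preset's parameter table
#' @return a [diabatic_model()] carrying preset metadata: `initial` (default
#'   initial nuclear/electronic state), `grid` (default quantum grid
#'   `c(xmin, xmax, n)`), and `defaults` (suggested time steps, fs)
#' @export
build_model <- function(preset, ...) {
  if (is.list(preset)) {
    tab <- utils::modifyList(preset, list(...))
    return(do.call(diabatic_model, tab))
  }
  m <- switch(preset,
    avoided_crossing_2s = .preset_avoided_crossing(),
    ibr_surrogate_3s    = .preset_ibr_surrogate(),
    tully3_sloped       = .preset_tully3(),
    lvc_nd              = .preset_lvc(),
    stop("unknown preset: ", preset)
  )
  m
}

.preset_avoided_crossing <- function() {
  m <- diabatic_model(
    n_states = 2, masses = 2000,
    terms = list(
      list(i = 1, j = 1, type = "exp", A = 0.03, a = 1.0, x0 = 2),
      list(i = 2, j = 2, type = "exp", A = 0.10, a = 1.5, x0 = 2),
      list(i = 2, j = 2, type = "const", c = -0.005),
      list(i = 1, j = 2, type = "const", c = 0.002)
    ),
    operators = list(
      dipole = function(x) matrix(c(0.1 * x, 0.05, 0.05, 0.3 * x), 2, 2)
    ),
    name = "avoided_crossing_2s"
  )
  m$grid <- c(-2.0, 31.0, 1024)
  ## minimum-uncertainty Gaussian released on the upper (first) diabat
  m$initial <- list(type = "gaussian", x0 = 2.3,
                    sigma = 1 / sqrt(2 * 2000 * 0.005), p0 = 0,
                    diabatic_coefficients = c(1, 0))
  m$defaults <- list(dt_fs = 0.1, dt_quantum_fs = 0.01, t_max_fs = 35)
  m
}

.preset_ibr_surrogate <- function() {
  ## masses and ground-state curvature give sigma = 1/sqrt(2*mu*omega)
  ## = 6.906e-2 bohr for mu = 89380 m_e, omega = 1.173e-3 hartree
  mu <- 89380
  omega1 <- 1.173e-3
  D1 <- 0.07
  a1 <- omega1 * sqrt(mu / (2 * D1))
  m <- diabatic_model(
    n_states = 3, masses = mu,
    terms = list(
      list(i = 1, j = 1, type = "morse", D = D1, a = a1, x0 = 4.666),
      list(i = 2, j = 2, type = "morse", D = 0.03, a = 0.8, x0 = 5.8),
      list(i = 2, j = 2, type = "const", c = 0.05),
      list(i = 3, j = 3, type = "exp", A = 0.2914, a = 2.0, x0 = 4.0),
      list(i = 3, j = 3, type = "const", c = 0.058),
      list(i = 1, j = 2, type = "const", c = 1e-4),
      list(i = 1, j = 3, type = "const", c = 1e-4),
      list(i = 2, j = 3, type = "const", c = 1.5e-3)
    ),
    name = "ibr_surrogate_3s"
  )
  m$grid <- c(3.5, 16.0, 1024)
  ## promotion of the diabatic ground-state wave function onto diabat 2
  m$initial <- list(type = "ground_state", ref_state = 1,
                    diabatic_coefficients = c(0, 1, 0))
  m$defaults <- list(dt_fs = 0.1, dt_quantum_fs = 0.01, t_max_fs = 150)
  m
}

.preset_tully3 <- function() {
  m <- diabatic_model(
    n_states = 2, masses = 2000,
    terms = list(
      list(i = 1, j = 1, type = "const", c = 0.01),
      list(i = 1, j = 1, type = "linear", k = -0.002, x0 = 0),
      list(i = 2, j = 2, type = "const", c = 0.02),
      list(i = 2, j = 2, type = "linear", k = -0.004, x0 = 0),
      list(i = 1, j = 2, type = "gauss", A = 0.002, a = 1.0, x0 = 5)
    ),
    name = "tully3_sloped"
  )
  m$grid <- c(-4.0, 24.0, 1024)
  m$initial <- list(type = "gaussian", x0 = 2, sigma = 0.25, p0 = 10,
                    diabatic_coefficients = c(0, 1))
  m$defaults <- list(dt_fs = 0.1, dt_quantum_fs = 0.01, t_max_fs = 60)
  m
}

.preset_lvc <- function() {
  omega <- c(0.004, 0.006, 0.009)
  w <- array(0, c(2, 2, 3))
  w[, , 1] <- matrix(c(0, 0.003, 0.003, 0), 2, 2)   # coupling mode
  w[, , 2] <- matrix(c(0, 0, 0, 0.003), 2, 2)       # tuning mode
  w[, , 3] <- matrix(c(0, 0, 0, 0.004), 2, 2)       # tuning mode
  m <- diabatic_model(
    n_states = 2, masses = c(1, 1, 1),
    lvc = list(omega = omega, v0 = diag(c(0, 0.06)), w = w),
    normal_modes = normal_mode_spec(omega),
    name = "lvc_nd"
  )
  m$initial <- list(type = "harmonic_wigner",
                    diabatic_coefficients = c(0, 1))
  m$defaults <- list(dt_fs = 0.2, t_max_fs = 100)
  m
}

#' Read a diabatic model from a YAML configuration file
#'
#' The file holds either `preset: <name>` or a full parameter table with
#' `n_states`, `masses`, and a `terms` sequence (see [diabatic_model()]).
#'
#' @param path path to a YAML file
#' @return a [diabatic_model()]
#' @export
read_model_config <- function(path) {
  if (!file.exists(path)) stop("model config not found: ", path)
  cfg <- yaml::read_yaml(path)
  if (!is.null(cfg$preset)) return(build_model(cfg$preset))
  allowed <- c("n_states", "masses", "terms", "lvc", "name")
  unknown <- setdiff(names(cfg), allowed)
  if (length(unknown)) {
    stop("unknown model config key(s): ", paste(unknown, collapse = ", "))
  }
  do.call(diabatic_model, cfg)
}
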