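#' Ensemble of initial conditions for trajectory dynamics
#'
#' Positions, momenta (atomic units) and initial complex electronic
#' coefficients, one row per sample.  Electronic coefficients are normalized
#' per sample.
#'
#' @param positions numeric matrix `n x n_dof` (bohr)
#' @param momenta numeric matrix `n x n_dof` (a.u.)
#' @param coefficients complex matrix `n x n_states`, or a single vector
#'   recycled to all samples; normalized row-wise
#' @param seed RNG seed used to generate the ensemble (recorded)
#' @param basis `"diabatic"` (default) or `"adiabatic"`: the electronic basis
#'   in which the coefficients are stated
#' @return object of class `initial_ensemble`
#' @export
initial_ensemble <- function(positions, momenta, coefficients, seed = NA,
                             basis = c("diabatic", "adiabatic")) {
  basis <- match.arg(basis)
  positions <- as.matrix(positions)
  momenta <- as.matrix(momenta)
  stopifnot(all(dim(positions) == dim(momenta)))
  n <- nrow(positions)
  if (is.null(dim(coefficients))) {
    coefficients <- matrix(as.complex(coefficients), n,
                           length(coefficients), byrow = TRUE)
  }
  coefficients <- matrix(as.complex(coefficients), nrow = n)
  nrm <- sqrt(rowSums(abs(coefficients)^2))
  if (any(nrm == 0)) stop("non-normalizable electronic coefficients")
  coefficients <- coefficients / nrm
  structure(list(positions = positions, momenta = momenta,
                 coefficients = coefficients, n = n, seed = seed,
                 basis = basis),
            class = "initial_ensemble")
}

#' @export
print.initial_ensemble <- function(x, ...) {
  cat(sprintf("<initial_ensemble> %d samples, %d dof, %d electronic states (%s basis, seed %s)\n",
              x$n, ncol(x$positions), ncol(x$coefficients), x$basis,
              format(x$seed)))
  invisible(x)
}

#' Zero-temperature harmonic Wigner sampling
#'
#' Samples the ground-state Wigner distribution of the harmonic normal-mode
#' Hamiltonian: per mode \eqn{\alpha}, the mass-weighted coordinate is drawn
#' from \eqn{N(0, 1/(2\omega_\alpha))} and the mass-weighted momentum from
#' \eqn{N(0, \omega_\alpha/2)} (variances), then transformed back to Cartesian
#' positions and momenta through the mode vectors and masses.
#'
#' @param normal_modes a [normal_mode_spec()]
#' @param n number of samples
#' @param seed RNG seed (same seed, same ensemble)
#' @param coefficients initial electronic coefficients passed to
#'   [initial_ensemble()] (default: state 1 populated; the state count cannot
#'   be inferred here, so pass the config's amplitudes for multi-state runs)
#' @return an [initial_ensemble()]
#' @export
harmonic_wigner_sample <- function(normal_modes, n, seed,
                                   coefficients = c(1)) {
  if (!inherits(normal_modes, "normal_mode_spec")) {
    stop("missing NormalModeSpec")
  }
  stopifnot(n >= 1)
  set.seed(seed)
  om <- normal_modes$frequencies
  nm <- normal_modes$n_modes
  q <- matrix(stats::rnorm(n * nm, sd = rep(sqrt(1 / (2 * om)), each = n)),
              n, nm)
  p <- matrix(stats::rnorm(n * nm, sd = rep(sqrt(om / 2), each = n)),
              n, nm)
  V <- normal_modes$vectors
  sqm <- sqrt(normal_modes$masses)
  ## Q = V q (mass-weighted Cartesian); R = M^{-1/2} Q; P = M^{1/2} V p
  R <- sweep(q %*% t(V), 2, sqm, "/")
  P <- sweep(p %*% t(V), 2, sqm, "*")
  initial_ensemble(R, P, coefficients, seed = seed)
}

#' Wigner transform of a 1-D grid wavefunction
#'
#' Evaluates \eqn{W(x,p) = \frac{1}{\pi}\int \psi^*(x+y)\,\psi(x-y)\,
#' e^{2ipy}\,dy} on the position grid of `wf` and the conjugate momentum grid
#' \eqn{p_l = \pi l/(N \Delta x)}, by FFT over the separation coordinate.
#'
#' @param wf single-column [grid_wavefunction()]
#' @return list with `x`, `p`, and the real matrix `W` (`length(x)` rows)
#' @export
wigner_transform <- function(wf) {
  psi <- wf$psi[, 1]
  n <- length(psi)
  dx <- wf$dx
  W <- matrix(0, n, n)
  idx <- seq_len(n)
  for (k in idx) {
    m <- 0:(n - 1)
    mm <- ifelse(m <= n / 2, m, m - n)        # signed separation index
    ip <- k + mm
    im <- k - mm
    g <- complex(length.out = n)
    ok <- ip >= 1 & ip <= n & im >= 1 & im <= n
    g[ok] <- Conj(psi[ip[ok]]) * psi[im[ok]]
    W[k, ] <- Re(stats::fft(g, inverse = TRUE)) * dx / pi
  }
  l <- 0:(n - 1)
  ll <- ifelse(l <= n / 2, l, l - n)
  p <- pi * ll / (n * dx)
  ord <- order(p)
  list(x = wf$x, p = p[ord], W = W[, ord])
}

#' Sample initial conditions from a numerical Wigner distribution
#'
#' Computes the Wigner function of a 1-D wavefunction on its grid and draws
#' `(x, p)` samples proportionally to the Wigner value over all cells whose
#' value exceeds `floor` (default `1e-10`); cells below the floor, including
#' all negative cells, are disregarded.  Intended for (positive-Wigner)
#' ground states.
#'
#' @param wf single-column [grid_wavefunction()] (e.g. from
#'   [fourier_grid_ground_state()])
#' @param n number of samples
#' @param seed RNG seed
#' @param floor Wigner-value floor below which cells are disregarded
#' @param coefficients initial electronic coefficients (see
#'   [harmonic_wigner_sample()])
#' @return an [initial_ensemble()]
#' @export
grid_wigner_sample <- function(wf, n, seed, floor = 1e-10,
                               coefficients = c(1)) {
  stopifnot(floor >= 0, n >= 1)
  wt <- wigner_transform(wf)
  keep <- which(wt$W > floor)
  if (length(keep) == 0) {
    stop("no Wigner cell exceeds the floor (", format(floor),
         "): degenerate or all-negative Wigner table")
  }
  wts <- wt$W[keep]
  set.seed(seed)
  cells <- sample(keep, n, replace = TRUE, prob = wts)
  ci <- (cells - 1) %% nrow(wt$W) + 1          # x index
  cj <- (cells - 1) %/% nrow(wt$W) + 1         # p index
  dxc <- wt$x[2] - wt$x[1]
  dpc <- wt$p[2] - wt$p[1]
  xs <- wt$x[ci] + stats::runif(n, -0.5, 0.5) * dxc
  ps <- wt$p[cj] + stats::runif(n, -0.5, 0.5) * dpc
  initial_ensemble(matrix(xs, ncol = 1), matrix(ps, ncol = 1),
                   coefficients, seed = seed)
}

#' Width parameters of the decoherence model
#'
#' Derives the width specification used by the FM/PFM decoherence rates:
#' for a multidimensional [normal_mode_spec()], the common frequency is the
#' geometric mean of the nonzero normal-mode frequencies,
#' \eqn{\omega = (\prod_\alpha \omega_\alpha)^{1/N_D}}; for a one-dimensional
#' [initial_ensemble()], the coordinate width \eqn{\sigma} is the sample
#' standard deviation of the bond coordinate.
#'
#' @param x a `normal_mode_spec` or a 1-dof `initial_ensemble`
#' @param mu reduced mass to record alongside a 1-D width (optional)
#' @return object of class `width_spec`: list with either `omega` and `n_d`,
#'   or `sigma` and `mu`
#' @export
width_parameters <- function(x, mu = NULL) {
  if (inherits(x, "normal_mode_spec")) {
    om <- x$frequencies
    if (any(om == 0)) stop("zero frequencies must be removed beforehand")
    spec <- list(omega = exp(mean(log(om))), n_d = length(om))
  } else if (inherits(x, "initial_ensemble")) {
    if (ncol(x$positions) != 1L) {
      stop("sample-based width requires a one-dimensional ensemble")
    }
    spec <- list(sigma = stats::sd(x$positions[, 1]), mu = mu)
  } else {
    stop("x must be a normal_mode_spec or an initial_ensemble")
  }
  structure(spec, class = "width_spec")
}

#' Write / read an initial-condition ensemble as CSV
#'
#' One row per sample: positions, momenta, and Re/Im of each electronic
#' coefficient, so that all trajectory ensembles (and the quantum reference)
#' can be run from a single stored set of initial conditions.
#'
#' @param ens an [initial_ensemble()]
#' @param path CSV file path
#' @return `write_ensemble_csv` returns `path` invisibly;
#'   `read_ensemble_csv` returns an [initial_ensemble()]
#' @export
write_ensemble_csv <- function(ens, path) {
  nd <- ncol(ens$positions); ns <- ncol(ens$coefficients)
  df <- data.frame(ens$positions, ens$momenta,
                   Re(ens$coefficients), Im(ens$coefficients))
  names(df) <- c(paste0("R", seq_len(nd)), paste0("P", seq_len(nd)),
                 paste0("re_c", seq_len(ns)), paste0("im_c", seq_len(ns)))
  attr(df, "seed") <- ens$seed
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_ensemble_csv
#' @param n_dof,basis structure of the stored ensemble (CSV stores no
#'   metadata beyond column names)
#' @export
read_ensemble_csv <- function(path, n_dof = 1L,
                              basis = c("diabatic", "adiabatic")) {
  df <- utils::read.csv(path)
  nd <- n_dof
  ns <- (ncol(df) - 2 * nd) / 2
  R <- as.matrix(df[, seq_len(nd), drop = FALSE])
  P <- as.matrix(df[, nd + seq_len(nd), drop = FALSE])
  cc <- as.matrix(df[, 2 * nd + seq_len(ns), drop = FALSE]) +
    1i * as.matrix(df[, 2 * nd + ns + seq_len(ns), drop = FALSE])
  initial_ensemble(R, P, cc, basis = match.arg(basis))
}
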