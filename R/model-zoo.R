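#' Construct an analytic diabatic model Hamiltonian
#'
#' A `diabatic_model` holds a real symmetric diabatic potential matrix
#' \eqn{V(R)} (hartree), its analytic gradient \eqn{\nabla V(R)}
#' (hartree/bohr), and the nuclear masses (electron masses), for either a
#' one-dimensional model built from elementary potential terms or a
#' multidimensional linear-vibronic-coupling (LVC) model.
#'
#' One-dimensional models are specified as a list of terms, each a list with
#' integer state indices `i`, `j`, a `type`, and parameters:
#' \describe{
#'   \item{`const`}{`c`: constant \eqn{c}}
#'   \item{`linear`}{`k`, `x0`: \eqn{k (x - x_0)}}
#'   \item{`harmonic`}{`k`, `x0`: \eqn{\tfrac12 k (x - x_0)^2}}
#'   \item{`morse`}{`D`, `a`, `x0`: \eqn{D (1 - e^{-a(x - x_0)})^2}}
#'   \item{`exp`}{`A`, `a`, `x0`: \eqn{A e^{-a(x - x_0)}}}
#'   \item{`gauss`}{`A`, `a`, `x0`: \eqn{A e^{-a (x - x_0)^2}}}
#'   \item{`tanh`}{`A`, `b`, `x0`: \eqn{A \tanh(b (x - x_0))}}
#' }
#' Terms given for element \eqn{(i,j)} with \eqn{i \ne j} are mirrored onto
#' \eqn{(j,i)}; if both orderings are specified they must agree, otherwise the
#' coupling table is non-symmetric and an error is raised.
#'
#' LVC models use positions interpreted as (dimensionless when `masses = 1`)
#' normal-mode displacements \eqn{Q} with
#' \deqn{V(Q) = V_0 + \sum_\alpha W_\alpha Q_\alpha
#'       + \tfrac12 \sum_\alpha \omega_\alpha^2 Q_\alpha^2 \, I}
#' where `v0` and each `w[, , alpha]` are real symmetric matrices.
#'
#' @param n_states number of electronic states (>= 2)
#' @param masses nuclear mass per degree of freedom, electron masses
#' @param terms list of term specifications (1-D models)
#' @param lvc list with `omega`, `v0`, `w` (multidimensional LVC models)
#' @param operators optional named list of functions `R -> n_states x
#'   n_states` real symmetric matrix (model observables, e.g. a dipole)
#' @param normal_modes optional [normal_mode_spec()]
#' @param name optional model name
#' @return an object of class `diabatic_model` with elements `n_states`,
#'   `n_dof`, `masses`, `V(R)`, `dV(R)` (returning an
#'   `n_states x n_states x n_dof` array), and the specification itself
#' @seealso [build_model()] for named presets
#' @export
diabatic_model <- function(n_states, masses, terms = NULL, lvc = NULL,
                           operators = NULL, normal_modes = NULL,
                           name = "custom") {
  if (n_states < 2L) stop("a diabatic model needs at least 2 states")
  if (any(!is.finite(masses)) || any(masses <= 0)) {
    stop("missing or non-positive mass")
  }
  if (is.null(terms) == is.null(lvc)) {
    stop("give exactly one of `terms` (1-D) or `lvc` (multi-D)")
  }
  if (!is.null(terms)) {
    if (length(masses) != 1L) stop("term-based models are one-dimensional")
    spec <- .terms_cspec(n_states, terms)
    kind <- "terms1d"
  } else {
    spec <- .lvc_cspec(n_states, masses, lvc)
    kind <- "lvc"
  }
  m <- structure(list(
    n_states = as.integer(n_states),
    n_dof = length(masses),
    masses = as.numeric(masses),
    kind = kind,
    cspec = spec,
    operators = operators,
    normal_modes = normal_modes,
    name = name
  ), class = "diabatic_model")
  m$V <- function(R) model_potential(m, R)
  m$dV <- function(R) model_gradient_matrix(m, R)
  ## symmetry of V is structural for both kinds; spot-check anyway
  Vt <- m$V(rep(0.5, m$n_dof))
  if (max(abs(Vt - t(Vt))) != 0) stop("non-symmetric coupling table")
  m
}

.term_types <- c(const = 1, linear = 2, harmonic = 3, morse = 4,
                 exp = 5, gauss = 6, tanh = 7)

## canonicalize the term list into a numeric matrix (i, j, type, p1, p2, p3)
.terms_cspec <- function(n_states, terms) {
  rows <- lapply(terms, function(tm) {
    i <- as.integer(tm$i); j <- as.integer(tm$j)
    if (is.na(i) || is.na(j) || i < 1 || j < 1 || i > n_states ||
        j > n_states) {
      stop("term state indices out of range")
    }
    ty <- .term_types[[tm$type]]
    p <- switch(tm$type,
      const    = c(tm$c, 0, 0),
      linear   = c(tm$k, tm$x0, 0),
      harmonic = c(tm$k, tm$x0, 0),
      morse    = c(tm$D, tm$a, tm$x0),
      exp      = c(tm$A, tm$a, tm$x0),
      gauss    = c(tm$A, tm$a, tm$x0),
      tanh     = c(tm$A, tm$b, tm$x0),
      stop("unknown term type: ", tm$type))
    if (any(!is.finite(p))) stop("incomplete parameters for term type ", tm$type)
    c(i, j, ty, p)
  })
  tab <- do.call(rbind, rows)
  colnames(tab) <- c("i", "j", "type", "p1", "p2", "p3")
  ## symmetry: off-diagonal terms act on the symmetric element pair {i, j}.
  ## If both (i,j) and (j,i) appear, their term sets must be identical.
  off <- tab[tab[, "i"] != tab[, "j"], , drop = FALSE]
  if (nrow(off) > 0) {
    key <- function(m, swap = FALSE) {
      ij <- if (swap) m[, c("j", "i"), drop = FALSE] else
        m[, c("i", "j"), drop = FALSE]
      apply(cbind(ij, m[, 3:6, drop = FALSE]), 1, paste, collapse = "|")
    }
    lower <- off[off[, "i"] > off[, "j"], , drop = FALSE]
    upper <- off[off[, "i"] < off[, "j"], , drop = FALSE]
    if (nrow(lower) > 0) {
      if (nrow(lower) != nrow(upper) ||
          !setequal(key(lower, swap = TRUE), key(upper))) {
        stop("non-symmetric coupling table")
      }
      ## keep only the upper representative; it is mirrored on evaluation
      tab <- tab[!(tab[, "i"] > tab[, "j"]), , drop = FALSE]
    }
  }
  list(terms = tab)
}

.lvc_cspec <- function(n_states, masses, lvc) {
  omega <- as.numeric(lvc$omega)
  ndof <- length(masses)
  if (length(omega) != ndof) stop("lvc$omega must match the number of dofs")
  v0 <- as.matrix(lvc$v0)
  w <- lvc$w
  if (is.null(w)) w <- array(0, c(n_states, n_states, ndof))
  stopifnot(all(dim(v0) == n_states), all(dim(w) == c(n_states, n_states, ndof)))
  if (max(abs(v0 - t(v0))) > 0) stop("non-symmetric coupling table")
  for (a in seq_len(ndof)) {
    if (max(abs(w[, , a] - t(w[, , a]))) > 0) stop("non-symmetric coupling table")
  }
  list(omega = omega, v0 = v0, w = w)
}

#' Evaluate the diabatic potential matrix
#' @param model a [diabatic_model()]
#' @param R position vector (length `n_dof`)
#' @return `n_states x n_states` symmetric matrix, hartree
#' @export
model_potential <- function(model, R) {
  ns <- model$n_states
  if (model$kind == "terms1d") {
    x <- R[[1L]]
    V <- matrix(0, ns, ns)
    tab <- model$cspec$terms
    for (r in seq_len(nrow(tab))) {
      v <- .eval_term(tab[r, "type"], tab[r, 4:6], x)
      i <- tab[r, "i"]; j <- tab[r, "j"]
      V[i, j] <- V[i, j] + v
      if (i != j) V[j, i] <- V[j, i] + v
    }
    V
  } else {
    cs <- model$cspec
    V <- cs$v0 + 0.5 * sum(cs$omega^2 * R^2) * diag(ns)
    for (a in seq_along(R)) V <- V + cs$w[, , a] * R[[a]]
    V
  }
}

#' Evaluate the gradient of the diabatic potential matrix
#' @inheritParams model_potential
#' @return `n_states x n_states x n_dof` array, hartree/bohr
#' @export
model_gradient_matrix <- function(model, R) {
  ns <- model$n_states
  nd <- model$n_dof
  G <- array(0, c(ns, ns, nd))
  if (model$kind == "terms1d") {
    x <- R[[1L]]
    tab <- model$cspec$terms
    for (r in seq_len(nrow(tab))) {
      g <- .eval_term_d(tab[r, "type"], tab[r, 4:6], x)
      i <- tab[r, "i"]; j <- tab[r, "j"]
      G[i, j, 1] <- G[i, j, 1] + g
      if (i != j) G[j, i, 1] <- G[j, i, 1] + g
    }
  } else {
    cs <- model$cspec
    for (a in seq_len(nd)) {
      G[, , a] <- cs$w[, , a] + cs$omega[a]^2 * R[[a]] * diag(ns)
    }
  }
  G
}

.eval_term <- function(type, p, x) {
  switch(type,
    p[1],                                  # const
    p[1] * (x - p[2]),                     # linear
    0.5 * p[1] * (x - p[2])^2,             # harmonic
    p[1] * (1 - exp(-p[2] * (x - p[3])))^2,# morse
    p[1] * exp(-p[2] * (x - p[3])),        # exp
    p[1] * exp(-p[2] * (x - p[3])^2),      # gauss
    p[1] * tanh(p[2] * (x - p[3])))        # tanh
}

.eval_term_d <- function(type, p, x) {
  switch(type,
    0,
    p[1],
    p[1] * (x - p[2]),
    {e <- exp(-p[2] * (x - p[3])); 2 * p[1] * (1 - e) * p[2] * e},
    -p[2] * p[1] * exp(-p[2] * (x - p[3])),
    -2 * p[2] * (x - p[3]) * p[1] * exp(-p[2] * (x - p[3])^2),
    p[1] * p[2] / cosh(p[2] * (x - p[3]))^2)
}

#' Normal-mode specification
#'
#' Frequencies and orthonormal mode vectors of the nonzero-frequency
#' vibrational subspace, used for harmonic Wigner sampling and to derive the
#' common frequency parameter of the PFM decoherence rate.
#'
#' @param frequencies strictly positive harmonic frequencies, atomic units
#' @param vectors matrix with orthonormal mode vectors as columns (defaults to
#'   the identity, i.e. positions already are normal-mode displacements)
#' @param masses mass per Cartesian degree of freedom, electron masses
#' @return object of class `normal_mode_spec`
#' @export
normal_mode_spec <- function(frequencies, vectors = NULL, masses = NULL) {
  frequencies <- as.numeric(frequencies)
  if (any(frequencies <= 0)) stop("all stored frequencies must be positive")
  n <- length(frequencies)
  if (is.null(vectors)) vectors <- diag(n)
  vectors <- as.matrix(vectors)
  if (ncol(vectors) != n) stop("one mode vector per frequency required")
  ortho <- crossprod(vectors)
  if (max(abs(ortho - diag(n))) > 1e-10) {
    stop("mode vectors must be orthonormal (tolerance 1e-10)")
  }
  if (is.null(masses)) masses <- rep(1, nrow(vectors))
  structure(list(frequencies = frequencies, vectors = vectors,
                 n_modes = n, masses = as.numeric(masses)),
            class = "normal_mode_spec")
}

#' Adiabatize a diabatic potential matrix
#'
#' Eigendecomposition of the real symmetric diabatic matrix at one geometry.
#' Energies are returned ascending; each eigenvector column is gauged so that
#' its largest-magnitude component is positive (temporal phase continuity
#' along a trajectory is handled by the propagator through overlap tracking,
#' not here).
#'
#' @param V real symmetric matrix (hartree), or a [diabatic_model()] together
#'   with a position `R`
#' @param R position at which to evaluate `V` when a model is given
#' @return object of class `adiabatic_point`: list with `energies` (ascending),
#'   `W` (orthogonal matrix, eigenvector columns in the diabatic basis), and
#'   `position`
#' @export
adiabatize <- function(V, R = NULL) {
  if (inherits(V, "diabatic_model")) {
    stopifnot(!is.null(R))
    V <- model_potential(V, R)
  }
  V <- as.matrix(V)
  if (max(abs(V - t(V))) > 1e-12 * max(1, max(abs(V)))) {
    stop("adiabatize: input matrix is not symmetric")
  }
  e <- eigen((V + t(V)) / 2, symmetric = TRUE)
  idx <- order(e$values)
  En <- e$values[idx]
  W <- e$vectors[, idx, drop = FALSE]
  for (k in seq_len(ncol(W))) {
    pk <- which.max(abs(W[, k]))
    if (W[pk, k] < 0) W[, k] <- -W[, k]
  }
  structure(list(energies = En, W = W, position = R),
            class = "adiabatic_point")
}

#' Adiabatic energy gradient by the Hellmann-Feynman rule
#'
#' \eqn{\nabla E_i = w_i^T (\nabla V) w_i} with \eqn{w_i} the adiabatic
#' eigenvector; the force on the nuclei is the negative gradient.  Requires a
#' non-degenerate eigenvalue at `R`.
#'
#' @param model a [diabatic_model()]
#' @param R position vector
#' @param state adiabatic state index (1-based, ascending energy)
#' @param gap_tol degeneracy tolerance in hartree (default `1e-10`); an error
#'   is raised when the smallest gap to a neighbouring state is below it, in
#'   which case the caller may fall back to finite differences of the
#'   adiabatized energies
#' @return gradient vector of length `n_dof`, hartree/bohr
#' @export
adiabatic_gradient <- function(model, R, state, gap_tol = 1e-10) {
  ap <- adiabatize(model, R = R)
  En <- ap$energies
  if (state < 1 || state > model$n_states) stop("state index out of range")
  gaps <- abs(En[state] - En[-state])
  if (any(gaps < gap_tol)) {
    stop("degenerate eigenvalues at R (gap below tolerance); ",
         "use finite differences of the adiabatized energies instead")
  }
  w <- ap$W[, state]
  G <- model_gradient_matrix(model, R)
  vapply(seq_len(model$n_dof),
         function(a) drop(crossprod(w, G[, , a] %*% w)), numeric(1))
}

#' @export
print.diabatic_model <- function(x, ...) {
  cat(sprintf("<diabatic_model '%s'>: %d states, %d dof (%s)\n",
              x$name, x$n_states, x$n_dof, x$kind))
  cat("  masses [m_e]:", format(x$masses, digits = 6), "\n")
  if (!is.null(x$normal_modes)) {
    cat("  normal modes [E_h]:",
        format(x$normal_modes$frequencies, digits = 4), "\n")
  }
  invisible(x)
}

#' @export
print.adiabatic_point <- function(x, ...) {
  cat("<adiabatic_point> energies [E_h]:",
      format(x$energies, digits = 8), "\n")
  invisible(x)
}

#' Plot the adiabatic potential curves of a one-dimensional model
#' @param x a 1-dof [diabatic_model()]
#' @param from,to,n plotting grid (bohr)
#' @param ... passed to [graphics::matplot()]
#' @export
plot.diabatic_model <- function(x, from = NULL, to = NULL, n = 400, ...) {
  if (x$n_dof != 1L) stop("plotting implemented for 1-dof models only")
  gs <- if (is.null(x$grid)) c(3.5, 11) else x$grid[1:2]
  if (is.null(from)) from <- gs[1]
  if (is.null(to)) to <- gs[2]
  xs <- seq(from, to, length.out = n)
  E <- t(vapply(xs, function(xx) adiabatize(x, R = xx)$energies,
                numeric(x$n_states)))
  graphics::matplot(xs, E, type = "l", lty = 1,
                    xlab = "bond length [bohr]",
                    ylab = "adiabatic energy [hartree]", ...)
  invisible(E)
}
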