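#' Unit conversion constants
#'
#' All internal quantities are in Hartree atomic units (hartree, bohr,
#' electron mass, atomic time unit).  Configuration files may state times in
#' femtoseconds and masses in unified atomic mass units; these constants
#' perform the conversion.
#'
#' * `au_time_per_fs`: atomic time units per femtosecond
#'   (1 fs = 41.341374575751 a.u.).
#' * `me_per_amu`: electron masses per unified atomic mass unit
#'   (1 amu = 1822.888486209 m_e).
#' * `ev_per_hartree`: electron volts per hartree (27.211386245988 eV).
#'
#' @name units
#' @examples
#' 0.1 * surfhop::au_time_per_fs   # a 0.1 fs nuclear step in atomic units
NULL

#' @rdname units
#' @export
au_time_per_fs <- 41.341374575751

#' @rdname units
#' @export
me_per_amu <- 1822.888486209

#' @rdname units
#' @export
ev_per_hartree <- 27.211386245988

#' Convert femtoseconds to atomic time units
#' @param t_fs time in femtoseconds
#' @return time in atomic units
#' @export
fs_to_au <- function(t_fs) t_fs * au_time_per_fs

#' Convert atomic time units to femtoseconds
#' @param t_au time in atomic units
#' @return time in femtoseconds
#' @export
au_to_fs <- function(t_au) t_au / au_time_per_fs

#' Convert unified atomic mass units to electron masses
#' @param m_amu mass in amu
#' @return mass in electron masses (atomic units)
#' @export
amu_to_me <- function(m_amu) m_amu * me_per_amu

#' Average of |cos| over the circle
#'
#' The isotropic-angle average of the modulus of the projection cosine,
#' \eqn{\frac{1}{2\pi}\int_0^{2\pi} |\cos\vartheta|\, d\vartheta = 2/\pi},
#' used to relate trajectory-velocity-projected force and momentum differences
#' to the moduli of the full mass-weighted difference vectors.
#'
#' @param numeric if `TRUE` (default `FALSE`), evaluate the defining integral
#'   by quadrature instead of returning the closed form; useful as a
#'   self-check.
#' @return the scalar \eqn{2/\pi}
#' @export
cos_angle_average <- function(numeric = FALSE) {
  if (numeric) {
    stats::integrate(function(th) abs(cos(th)), 0, 2 * pi,
                     rel.tol = 1e-12)$value / (2 * pi)
  } else {
    2 / pi
  }
}
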