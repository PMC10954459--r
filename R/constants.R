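# Physical constants in the package's internal unit system:
# lengths nm, forces pN, energies kBT or pN*nm, charges e, angles degrees
# at the user surface (radians inside the Eq.-of-state fits).

#' Boltzmann constant in pN nm / K
#' @keywords internal
.kB <- 0.0138065

#' Thermal energy at temperature T
#'
#' @param T temperature in K (default 298 K, where kBT = 4.114 pN nm).
#' @return kBT in pN nm.
#' @export
kBT <- function(T = 298) .kB * T

#' Avogadro constant per millimolar per nm^3
#'
#' 1 mM corresponds to this many particles per nm^3.
#' @keywords internal
.mM_per_nm3 <- 6.02214076e-4

#' Bjerrum length
#'
#' Separation at which two unit charges interact with thermal energy kBT,
#' l_B = e^2 / (4 pi eps0 eps_s kB T).  About 0.72 nm in water at 298 K.
#'
#' @param T temperature in K.
#' @param eps_s relative dielectric constant of the solvent.
#' @return Bjerrum length in nm.
#' @export
bjerrumLength <- function(T = 298, eps_s = 78) {
  # e^2/(4 pi eps0) = 2.306994e-28 J m = 230.6994 (zJ nm); kB = 1.380649e-2 zJ/K
  230.6994 / (eps_s * 1.380649e-2 * T)
}

#' Seventh-order polynomial correction coefficients for the WLC
#' force-extension interpolation
#'
#' The correction coefficients alpha_2..alpha_7 of Bouchiat et al. (1999)
#' that reduce the residuals of the Marko-Siggia interpolation formula to
#' below 0.01\%.  Returned as a named numeric vector; pass
#' \code{markoSiggiaCoefficients()} (all zero) to recover the uncorrected
#' interpolation.
#'
#' @return named numeric vector of length 6 (alpha2..alpha7).
#' @export
bouchiatCoefficients <- function() {
  c(alpha2 = -0.5164228, alpha3 = -2.737418, alpha4 = 16.07497,
    alpha5 = -38.87607, alpha6 = 39.49944, alpha7 = -14.17718)
}

#' @rdname bouchiatCoefficients
#' @export
markoSiggiaCoefficients <- function() {
  c(alpha2 = 0, alpha3 = 0, alpha4 = 0, alpha5 = 0, alpha6 = 0, alpha7 = 0)
}

# Evaluate an expression with a temporary RNG seed, restoring the caller's
# RNG state afterwards.  seed = NULL leaves the RNG stream untouched.
withSeed <- function(seed, expr) {
  if (is.null(seed)) return(expr)
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  expr
}
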