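# Screened-Coulomb electrostatics and decomposition of bending energy into
# electrostatic and intrinsic (non-electrostatic) parts:
#   dE_el(theta)  = E_el(theta) - E_el(0)
#   dE_nel(theta) = dE_bend(theta) - dE_el(theta)
# with persistence lengths from quadratic fits dE/kBT = P theta^2 / 2 Lc.

#' Debye screening length of a 1:1 salt
#'
#' kappa^-1 = (8 pi l_B N_A c)^(-1/2); about 0.78 nm at 150 mM and 298 K.
#'
#' @param c_mM salt concentration in mM (> 0).
#' @param T temperature in K.
#' @param eps_s solvent dielectric constant.
#' @return Debye length in nm.
#' @export
debyeLength <- function(c_mM, T = 298, eps_s = 78) {
  if (any(c_mM <= 0)) stop("concentration must be > 0")
  lB <- bjerrumLength(T, eps_s)
  1 / sqrt(8 * pi * lB * c_mM * .mM_per_nm3)
}

#' Construct a screened-Coulomb electrostatic model
#'
#' @param c_mM salt concentration in mM.
#' @param T temperature in K.
#' @param eps_s solvent dielectric constant (default 78).
#' @param eps_m solute dielectric constant (default 8; recorded for PQR
#'   interoperability, unused by the screened-Coulomb energy).
#' @return an [ElectrostaticModel-class].
#' @export
electrostaticModel <- function(c_mM = 150, T = 298, eps_s = 78, eps_m = 8) {
  new("ElectrostaticModel", eps_s = eps_s, eps_m = eps_m,
      kappa_inv = debyeLength(c_mM, T, eps_s),
      l_B = bjerrumLength(T, eps_s), T = T)
}

#' Screened-Coulomb electrostatic energy of a conformation
#'
#' E_el = l_B * sum_{i<j} q_i q_j exp(-kappa r_ij) / r_ij in kBT, over the
#' charged phosphate sites of the frame.
#'
#' @param frame a [HelixFrame-class]; charges are
#'   \code{frame@phosphate_charge} on every phosphorus site.
#' @param model an [ElectrostaticModel-class].
#' @return energy in kBT.
#' @export
electrostaticEnergy <- function(frame, model) {
  stopifnot(is(frame, "HelixFrame"), is(model, "ElectrostaticModel"))
  pts <- rbind(frame@p1, frame@p2)
  q <- rep(frame@phosphate_charge, nrow(pts))
  .screenedCoulomb(pts, q, model)
}

# pairwise screened-Coulomb sum for arbitrary point charges
.screenedCoulomb <- function(pts, q, model) {
  if (all(q == 0)) return(0)
  d <- as.matrix(stats::dist(pts))
  if (any(d[upper.tri(d)] < 1e-9))
    stop("coincident charges: electrostatic energy undefined")
  kap <- 1 / model@kappa_inv
  qq <- outer(q, q)
  ut <- upper.tri(d)
  model@l_B * sum(qq[ut] * exp(-kap * d[ut]) / d[ut])
}

#' Electrostatic bending-energy profile
#'
#' dE_el(theta) = E_el(theta) - E_el(0) for a set of conformations with
#' matched charges, averaged over conformations per angle bin.
#'
#' @param frames list of bent [HelixFrame-class] conformations.
#' @param reference the straight (theta = 0) reference frame.
#' @param model an [ElectrostaticModel-class].
#' @param theta_deg optional per-frame bending angles; measured from each
#'   frame when omitted.
#' @param bin_deg bin width for conformational averaging (0 keeps one entry
#'   per frame).
#' @return data.frame with theta_deg, dE_el (kBT), n.
#' @export
deltaEel <- function(frames, reference, model, theta_deg = NULL,
                     bin_deg = 0) {
  stopifnot(is(reference, "HelixFrame"))
  if (!length(frames)) stop("need at least one bent conformation")
  if (abs(reference@phosphate_charge -
          frames[[1]]@phosphate_charge) > 1e-12)
    stop("reference and bent frames must carry the same charges")
  E0 <- electrostaticEnergy(reference, model)
  E <- vapply(frames, electrostaticEnergy, 0, model = model)
  if (is.null(theta_deg))
    theta_deg <- vapply(frames, bendingAngle, 0)
  dE <- E - E0
  if (bin_deg > 0) {
    b <- floor(theta_deg / bin_deg)
    agg <- tapply(dE, b, mean)
    nn <- tapply(dE, b, length)
    data.frame(theta_deg = (as.numeric(names(agg)) + 0.5) * bin_deg,
               dE_el = as.numeric(agg), n = as.numeric(nn))
  } else {
    data.frame(theta_deg = theta_deg, dE_el = dE, n = 1)
  }
}

#' Decompose bending energy into electrostatic and intrinsic parts
#'
#' Subtracts the electrostatic profile from the total bending-energy
#' profile pointwise (dE_nel = dE_bend - dE_el, an exact identity) and
#' converts all three profiles to persistence lengths by quadratic fits
#' dE/kBT = P theta^2 / (2 Lc).  For quadratic profiles the fitted values
#' satisfy P = P_el + P_nel.
#'
#' @param bend_profile data.frame with theta_deg and E_kBT (e.g. from
#'   [bendingEnergy()]); an optional count column weights the fits.
#' @param eel_profile data.frame with theta_deg and dE_el from [deltaEel()].
#' @param Lc segment contour length in nm.
#' @param intercept fit a free intercept (default TRUE).
#' @param min_count minimum bin count entering the fits when counts are
#'   present.
#' @return an [EnergyDecomposition-class].
#' @export
decomposeBendingEnergy <- function(bend_profile, eel_profile, Lc,
                                   intercept = TRUE, min_count = 1) {
  th_b <- round(bend_profile$theta_deg, 9)
  th_e <- round(eel_profile$theta_deg, 9)
  common <- intersect(th_b, th_e)
  if (!length(common))
    stop("bending and electrostatic profiles share no theta grid points")
  if (length(common) < length(th_b) && length(common) < length(th_e))
    message("profiles joined on ", length(common), " common theta bins")
  ib <- match(common, th_b); ie <- match(common, th_e)
  dEb <- bend_profile$E_kBT[ib]
  dEe <- eel_profile$dE_el[ie]
  dEn <- dEb - dEe
  counts <- if ("count" %in% names(bend_profile))
    bend_profile$count[ib] else rep(1, length(common))

  fitP <- function(y) .fitQuadratic(common, y, counts, Lc,
                                    min_count = min_count, q_max = 1,
                                    intercept = intercept, min_bins = 3)$P
  ok <- is.finite(dEb) & is.finite(dEe)
  P <- fitP(ifelse(ok, dEb, NA))
  P_el <- if (all(abs(dEe[ok]) < 1e-12)) 0 else fitP(ifelse(ok, dEe, NA))
  P_nel <- if (all(abs(dEe[ok]) < 1e-12)) P else fitP(ifelse(ok, dEn, NA))
  new("EnergyDecomposition", theta_deg = common, dE_bend = dEb,
      dE_el = dEe, dE_nel = dEn, P = P, P_el = P_el, P_nel = P_nel,
      Lc = Lc)
}
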