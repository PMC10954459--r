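#' @import methods
NULL

# ---------------------------------------------------------------------------
# HelixForm: canonical helical geometry (A-form dsRNA / B-form dsDNA)
# ---------------------------------------------------------------------------

#' Canonical helix geometry
#'
#' Describes an idealized duplex form: helical rise and twist per base pair,
#' the resting base-pair inclination, the radius of the phosphate helices and
#' the split of one helical pitch into the axial spans of the major and minor
#' grooves.  Two presets are provided by [helixForm()]: A-form (dsRNA) and
#' B-form (dsDNA).
#'
#' @slot name form label, "A" or "B".
#' @slot rise_per_bp helical rise in nm per base pair.
#' @slot twist_per_bp helical twist in degrees per base pair.
#' @slot inclination0 resting base-pair inclination in degrees.
#' @slot helical_radius radius of the phosphate helices in nm.
#' @slot groove_fractions named numeric, fractions of the pitch spanned
#'   axially by the major and minor grooves; must sum to 1.
#' @export
setClass("HelixForm",
  representation(
    name = "character",
    rise_per_bp = "numeric",
    twist_per_bp = "numeric",
    inclination0 = "numeric",
    helical_radius = "numeric",
    groove_fractions = "numeric"
  )
)

setValidity("HelixForm", function(object) {
  msg <- character()
  if (object@rise_per_bp <= 0) msg <- c(msg, "rise_per_bp must be > 0")
  if (object@twist_per_bp <= 0 || object@twist_per_bp >= 60)
    msg <- c(msg, "twist_per_bp must lie in (0, 60) degrees")
  if (object@helical_radius <= 0) msg <- c(msg, "helical_radius must be > 0")
  gf <- object@groove_fractions
  if (!all(c("major", "minor") %in% names(gf)))
    msg <- c(msg, "groove_fractions needs 'major' and 'minor' entries")
  else if (abs(sum(gf[c("major", "minor")]) - 1) > 1e-9)
    msg <- c(msg, "major + minor groove fractions must sum to 1")
  if (length(msg)) msg else TRUE
})

# ---------------------------------------------------------------------------
# HelixFrame: one conformation of a coarse duplex
# ---------------------------------------------------------------------------

#' One coarse-grained duplex conformation
#'
#' Holds, for each base pair: the two strands' phosphorus positions, the
#' base-pair reference point (origin) and an orthonormal base-pair triad
#' (normal, long axis, short axis).  All coordinates in nm.  The short axis
#' points toward the major-groove bisector; the long axis spans the pair.
#'
#' @slot p1,p2 n_bp x 3 matrices of phosphorus coordinates, strands 1 and 2.
#' @slot origin n_bp x 3 matrix of base-pair reference points.
#' @slot nrm,lng,shrt n_bp x 3 matrices of unit triad vectors per base pair.
#' @slot form the [HelixForm-class] the frame was built from.
#' @slot phosphate_charge charge per phosphate site in e (-1, or 0 for the
#'   electrically neutral construct).
#' @export
setClass("HelixFrame",
  representation(
    p1 = "matrix", p2 = "matrix", origin = "matrix",
    nrm = "matrix", lng = "matrix", shrt = "matrix",
    form = "HelixForm", phosphate_charge = "numeric"
  )
)

setValidity("HelixFrame", function(object) {
  n <- nrow(object@origin)
  mats <- list(p1 = object@p1, p2 = object@p2, nrm = object@nrm,
               lng = object@lng, shrt = object@shrt)
  for (nm in names(mats)) {
    if (!is.numeric(mats[[nm]]) || ncol(mats[[nm]]) != 3 || nrow(mats[[nm]]) != n)
      return(sprintf("slot '%s' must be an n_bp x 3 numeric matrix", nm))
  }
  if (n < 4) return("a HelixFrame needs at least 4 base pairs")
  TRUE
})

# ---------------------------------------------------------------------------
# HelixTrajectory: an ordered set of frames + ions
# ---------------------------------------------------------------------------

#' A trajectory of coarse duplex conformations
#'
#' Frames are stored as n_bp x 3 x n_frames arrays for compactness; use
#' [getFrame()] to extract a single [HelixFrame-class].  Ion records for all
#' frames live in one data.frame with columns
#' \code{frame, species, charge, x, y, z}.
#'
#' @slot p1,p2,origin,nrm,lng,shrt n_bp x 3 x n_frames numeric arrays.
#' @slot ions data.frame of ion records (possibly 0 rows).
#' @slot frameMeta per-frame metadata (generator angles etc.).
#' @slot form the construction [HelixForm-class].
#' @slot phosphate_charge charge per phosphate site in e.
#' @slot config the generator configuration list used to build the object.
#' @export
setClass("HelixTrajectory",
  representation(
    p1 = "array", p2 = "array", origin = "array",
    nrm = "array", lng = "array", shrt = "array",
    ions = "data.frame", frameMeta = "data.frame",
    form = "HelixForm", phosphate_charge = "numeric",
    config = "list"
  )
)

setValidity("HelixTrajectory", function(object) {
  d <- dim(object@origin)
  if (length(d) != 3 || d[2] != 3)
    return("coordinate slots must be n_bp x 3 x n_frames arrays")
  for (nm in c("p1", "p2", "nrm", "lng", "shrt"))
    if (!identical(dim(slot(object, nm)), d))
      return(sprintf("slot '%s' has mismatched dimensions", nm))
  if (nrow(object@ions) &&
      !all(c("frame", "species", "charge", "x", "y", "z") %in%
           colnames(object@ions)))
    return("ions needs columns frame, species, charge, x, y, z")
  TRUE
})

# ---------------------------------------------------------------------------
# BendingEnsemble / AngleHistogram
# ---------------------------------------------------------------------------

#' Ensemble of segment bending angles
#'
#' Bending angles theta (degrees) of fixed-contour-length helix segments,
#' pooled over trajectory frames or drawn directly from the worm-like-chain
#' angle density.
#'
#' @slot angles_deg numeric vector of bending angles in degrees, in
#'   \[0, 180\].
#' @slot segment_Lc contour length of the segments in nm.
#' @slot segment_bp segment length in base pairs (NA when sampled directly).
#' @slot meta provenance list (generator parameters, source, seed).
#' @export
setClass("BendingEnsemble",
  representation(
    angles_deg = "numeric", segment_Lc = "numeric",
    segment_bp = "numeric", meta = "list"
  )
)

setValidity("BendingEnsemble", function(object) {
  if (object@segment_Lc <= 0) return("segment_Lc must be > 0")
  a <- object@angles_deg
  if (length(a) && (min(a) < -1e-9 || max(a) > 180 + 1e-9))
    return("angles must lie in [0, 180] degrees")
  TRUE
})

#' Binned bending-angle distribution
#'
#' Histogram of bending angles with the 0.5 degree default bin width.
#' \code{density} is the probability density per degree, so that
#' sum(density) * bin width = 1.
#'
#' @slot breaks_deg bin edges in degrees.
#' @slot mids_deg bin centers in degrees.
#' @slot counts integer counts per bin.
#' @slot density probability density per degree.
#' @slot n total number of angles.
#' @export
setClass("AngleHistogram",
  representation(
    breaks_deg = "numeric", mids_deg = "numeric",
    counts = "numeric", density = "numeric", n = "numeric"
  )
)

setValidity("AngleHistogram", function(object) {
  if (length(object@mids_deg) != length(object@counts) ||
      length(object@counts) != length(object@density))
    return("mids, counts and density must have equal length")
  w <- diff(object@breaks_deg)
  if (object@n > 0 && abs(sum(object@density * w) - 1) > 1e-9)
    return("density must integrate to 1 over the bins")
  TRUE
})

# ---------------------------------------------------------------------------
# Force-extension data and fits
# ---------------------------------------------------------------------------

#' A single-molecule force-extension record
#'
#' @slot extension_nm measured extensions x in nm.
#' @slot force_pN applied forces F in pN (> 0).
#' @slot temperature_K bath temperature in K.
#' @slot molecule_id molecule label.
#' @slot ion salt species ("Na", "Li", ...).
#' @slot conc_mM salt concentration in mM.
#' @export
setClass("ForceExtensionCurve",
  representation(
    extension_nm = "numeric", force_pN = "numeric",
    temperature_K = "numeric", molecule_id = "character",
    ion = "character", conc_mM = "numeric"
  )
)

setValidity("ForceExtensionCurve", function(object) {
  if (length(object@extension_nm) != length(object@force_pN))
    return("extension and force must have equal length")
  if (any(object@force_pN <= 0)) return("forces must be > 0")
  if (any(object@extension_nm < 0)) return("extensions must be >= 0")
  TRUE
})

#' Result of a WLC force-extension fit
#'
#' @slot P fitted bending persistence length in nm.
#' @slot Lc fitted contour length in nm.
#' @slot se_P,se_Lc asymptotic standard errors in nm.
#' @slot rss residual sum of squares in log-force space.
#' @slot n_points number of points used.
#' @slot n_bp number of base pairs, if known (for rise = Lc/(n_bp - 1)).
#' @slot molecule_id molecule label carried over from the curve.
#' @export
setClass("WLCFitResult",
  representation(
    P = "numeric", Lc = "numeric", se_P = "numeric", se_Lc = "numeric",
    rss = "numeric", n_points = "numeric", n_bp = "numeric",
    molecule_id = "character"
  )
)

setValidity("WLCFitResult", function(object) {
  if (object@P <= 0) return("P must be > 0")
  if (object@Lc <= 0) return("Lc must be > 0")
  TRUE
})

# ---------------------------------------------------------------------------
# Electrostatics / decomposition
# ---------------------------------------------------------------------------

#' Screened-Coulomb electrostatic model
#'
#' Linearized Debye-Hueckel description of the solvent: uniform solvent
#' dielectric, exponential screening with the Debye length of the salt.  The
#' solute dielectric is recorded for interoperability (PQR export to a full
#' Poisson-Boltzmann solver) but unused by the screened-Coulomb energy.
#'
#' @slot eps_s solvent dielectric constant.
#' @slot eps_m solute dielectric constant (recorded, unused).
#' @slot kappa_inv Debye length in nm.
#' @slot l_B Bjerrum length in nm.
#' @slot T temperature in K.
#' @export
setClass("ElectrostaticModel",
  representation(
    eps_s = "numeric", eps_m = "numeric", kappa_inv = "numeric",
    l_B = "numeric", T = "numeric"
  )
)

setValidity("ElectrostaticModel", function(object) {
  if (object@eps_s <= 1) return("eps_s must be > 1")
  if (object@kappa_inv <= 0) return("kappa_inv must be > 0")
  TRUE
})

#' Decomposition of bending energy into electrostatic and intrinsic parts
#'
#' Holds the three energy profiles on a common bending-angle grid and the
#' persistence lengths obtained by quadratic fits of each profile.  The
#' intrinsic profile is the pointwise difference
#' dE_nel(theta) = dE_bend(theta) - dE_el(theta).
#'
#' @slot theta_deg bending-angle grid in degrees.
#' @slot dE_bend,dE_el,dE_nel energies in kBT on the grid.
#' @slot P,P_el,P_nel fitted persistence lengths in nm.
#' @slot Lc segment contour length used in the fits, nm.
#' @export
setClass("EnergyDecomposition",
  representation(
    theta_deg = "numeric", dE_bend = "numeric", dE_el = "numeric",
    dE_nel = "numeric", P = "numeric", P_el = "numeric", P_nel = "numeric",
    Lc = "numeric"
  )
)

setValidity("EnergyDecomposition", function(object) {
  n <- length(object@theta_deg)
  if (length(object@dE_bend) != n || length(object@dE_el) != n ||
      length(object@dE_nel) != n)
    return("profiles must share the theta grid")
  ok <- is.finite(object@dE_bend) & is.finite(object@dE_el)
  if (any(abs(object@dE_nel[ok] -
              (object@dE_bend[ok] - object@dE_el[ok])) > 1e-9))
    return("dE_nel must equal dE_bend - dE_el pointwise")
  TRUE
})

# ---------------------------------------------------------------------------
# Salt series and model fits
# ---------------------------------------------------------------------------

#' Salt-concentration series of persistence lengths
#'
#' @slot conc_mM salt concentrations in mM (positive, distinct).
#' @slot P_nm persistence lengths in nm.
#' @slot se_nm standard errors in nm (may be NA).
#' @slot ion ion species label.
#' @slot molecule molecule type label ("dsRNA"/"dsDNA").
#' @export
setClass("SaltSeries",
  representation(
    conc_mM = "numeric", P_nm = "numeric", se_nm = "numeric",
    ion = "character", molecule = "character"
  )
)

setValidity("SaltSeries", function(object) {
  if (any(object@conc_mM <= 0)) return("concentrations must be > 0")
  if (anyDuplicated(object@conc_mM)) return("concentrations must be distinct")
  if (length(object@conc_mM) != length(object@P_nm))
    return("conc and P must have equal length")
  TRUE
})

#' A fitted polyelectrolyte salt-dependence model
#'
#' @slot model "OSF" or "BJ".
#' @slot P_nel fitted non-electrostatic persistence length in nm.
#' @slot amplitude fitted electrostatic amplitude (model-specific units).
#' @slot se_P_nel,se_amplitude asymptotic standard errors.
#' @slot rss weighted residual sum of squares.
#' @slot residuals per-point residuals in nm.
#' @export
setClass("SaltModelFit",
  representation(
    model = "character", P_nel = "numeric", amplitude = "numeric",
    se_P_nel = "numeric", se_amplitude = "numeric", rss = "numeric",
    residuals = "numeric"
  )
)

setValidity("SaltModelFit", function(object) {
  if (!object@model %in% c("OSF", "BJ")) return("model must be OSF or BJ")
  if (object@P_nel <= 0) return("P_nel must be > 0")
  TRUE
})
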