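#' Number of base pairs
#' @param x a HelixFrame or HelixTrajectory.
#' @return integer count of base pairs.
#' @export
setGeneric("nBasePairs", function(x) standardGeneric("nBasePairs"))

#' Number of frames in a trajectory
#' @param x a HelixTrajectory.
#' @return integer frame count.
#' @export
setGeneric("nFrames", function(x) standardGeneric("nFrames"))

#' Fitted persistence length
#' @param x a fit-result object.
#' @return persistence length in nm.
#' @export
setGeneric("persistenceLength", function(x) standardGeneric("persistenceLength"))

#' Fitted contour length
#' @param x a fit-result object.
#' @return contour length in nm.
#' @export
setGeneric("contourLength", function(x) standardGeneric("contourLength"))

#' Bending angles of an ensemble
#' @param x a BendingEnsemble.
#' @return numeric vector of angles in degrees.
#' @export
setGeneric("angles", function(x) standardGeneric("angles"))

#' @describeIn nBasePairs base pairs in one conformation
#' @export
setMethod("nBasePairs", "HelixFrame", function(x) nrow(x@origin))

#' @describeIn nBasePairs base pairs per frame of a trajectory
#' @export
setMethod("nBasePairs", "HelixTrajectory", function(x) dim(x@origin)[1])

#' @describeIn nFrames frame count
#' @export
setMethod("nFrames", "HelixTrajectory", function(x) dim(x@origin)[3])

#' @describeIn persistenceLength from a WLC force-extension fit
#' @export
setMethod("persistenceLength", "WLCFitResult", function(x) x@P)

#' @describeIn contourLength from a WLC force-extension fit
#' @export
setMethod("contourLength", "WLCFitResult", function(x) x@Lc)

#' @describeIn angles angle vector in degrees
#' @export
setMethod("angles", "BendingEnsemble", function(x) x@angles_deg)

#' Extract one frame from a trajectory
#'
#' @param traj a [HelixTrajectory-class].
#' @param i frame index (1-based).
#' @return a [HelixFrame-class].
#' @export
getFrame <- function(traj, i) {
  stopifnot(is(traj, "HelixTrajectory"))
  if (i < 1 || i > nFrames(traj)) stop("frame index out of range")
  new("HelixFrame",
      p1 = traj@p1[, , i], p2 = traj@p2[, , i], origin = traj@origin[, , i],
      nrm = traj@nrm[, , i], lng = traj@lng[, , i], shrt = traj@shrt[, , i],
      form = traj@form, phosphate_charge = traj@phosphate_charge)
}

#' Ion records of one frame
#'
#' @param traj a [HelixTrajectory-class].
#' @param i frame index.
#' @return data.frame of ion records for that frame (0 rows if none).
#' @export
frameIons <- function(traj, i) {
  stopifnot(is(traj, "HelixTrajectory"))
  traj@ions[traj@ions$frame == i, , drop = FALSE]
}

setMethod("show", "HelixForm", function(object) {
  cat(sprintf("HelixForm '%s': rise %.3f nm, twist %.1f deg, incl %.1f deg, radius %.2f nm\n",
              object@name, object@rise_per_bp, object@twist_per_bp,
              object@inclination0, object@helical_radius))
  cat(sprintf("  axial groove fractions: major %.2f / minor %.2f of pitch\n",
              object@groove_fractions[["major"]],
              object@groove_fractions[["minor"]]))
})

setMethod("show", "HelixFrame", function(object) {
  cat(sprintf("HelixFrame: %d bp, %s-form, phosphate charge %+g e\n",
              nBasePairs(object), object@form@name, object@phosphate_charge))
})

setMethod("show", "HelixTrajectory", function(object) {
  cat(sprintf("HelixTrajectory: %d frames x %d bp (%s-form), %d ion records\n",
              nFrames(object), nBasePairs(object), object@form@name,
              nrow(object@ions)))
})

setMethod("show", "BendingEnsemble", function(object) {
  a <- object@angles_deg
  cat(sprintf("BendingEnsemble: %d angles, segment Lc %.3g nm", length(a),
              object@segment_Lc))
  if (!is.na(object@segment_bp)) cat(sprintf(" (%d bp)", object@segment_bp))
  if (length(a)) cat(sprintf("; mean %.2f deg, sd %.2f deg", mean(a), stats::sd(a)))
  cat("\n")
})

setMethod("show", "ForceExtensionCurve", function(object) {
  cat(sprintf("ForceExtensionCurve '%s': %d points, %g-%g pN, %s %g mM, %g K\n",
              object@molecule_id, length(object@force_pN),
              min(object@force_pN), max(object@force_pN),
              object@ion, object@conc_mM, object@temperature_K))
})

setMethod("show", "WLCFitResult", function(object) {
  cat(sprintf("WLC fit: P = %.2f +/- %.2f nm, Lc = %.1f +/- %.1f nm (n = %d)\n",
              object@P, object@se_P, object@Lc, object@se_Lc,
              as.integer(object@n_points)))
  if (!is.na(object@n_bp))
    cat(sprintf("  rise = Lc/(n_bp - 1) = %.4f nm/bp\n",
                object@Lc / (object@n_bp - 1)))
})

setMethod("show", "EnergyDecomposition", function(object) {
  cat(sprintf("Energy decomposition on %d theta bins (Lc = %.3g nm):\n",
              length(object@theta_deg), object@Lc))
  cat(sprintf("  P = %.2f nm, P_el = %.2f nm, P_nel = %.2f nm\n",
              object@P, object@P_el, object@P_nel))
})

setMethod("show", "SaltModelFit", function(object) {
  cat(sprintf("%s salt-model fit: P_nel = %.2f +/- %.2f nm, amplitude = %.3g, RSS = %.3g\n",
              object@model, object@P_nel, object@se_P_nel, object@amplitude,
              object@rss))
})

setMethod("show", "SaltSeries", function(object) {
  cat(sprintf("SaltSeries (%s, %s): %d concentrations, %g-%g mM\n",
              object@molecule, object@ion, length(object@conc_mM),
              min(object@conc_mM), max(object@conc_mM)))
})
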