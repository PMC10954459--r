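# Segment bending angles, angle histograms, and persistence length from
# the bending-angle distribution:
#   -ln(p(theta)/sin theta) = P theta^2 / (2 Lc)        (pdf route)
#   dE_bend(theta)/kBT      = -ln(p(theta)/sin theta)   (energy route)
# Both routes are weighted linear regressions of the left-hand side on
# theta^2/(2 Lc) with theta in radians; the slope is P in nm.

#' Central axis of a helix conformation
#'
#' One axis point per base pair: the base-pair reference point smoothed with
#' a 3-bp moving average (ends use the available partial window).  Tangents
#' per base step are the normalized differences of consecutive axis points.
#'
#' @param frame a [HelixFrame-class].
#' @return list with \code{points} (n x 3 axis polyline), \code{tangents}
#'   ((n-1) x 3 unit step tangents) and \code{tangent_bp} (n x 3 per-base-
#'   pair tangents, averaging the adjacent step tangents).
#' @export
centralAxis <- function(frame) {
  stopifnot(is(frame, "HelixFrame"))
  o <- frame@origin
  n <- nrow(o)
  if (n < 4) stop("need at least 4 base pairs")
  pts <- o
  if (n >= 3) {
    core <- (o[1:(n - 2), , drop = FALSE] + o[2:(n - 1), , drop = FALSE] +
             o[3:n, , drop = FALSE]) / 3
    pts <- rbind((o[1, ] + o[2, ]) / 2, core, (o[n - 1, ] + o[n, ]) / 2)
  }
  d <- pts[-1, , drop = FALSE] - pts[-n, , drop = FALSE]
  len <- sqrt(rowSums(d^2))
  if (any(len < 1e-12))
    stop("degenerate geometry: coincident base-pair centers")
  tg <- d / len
  tb <- rbind(tg[1, , drop = FALSE],
              (tg[-1, , drop = FALSE] + tg[-(n - 1), , drop = FALSE]),
              tg[n - 1, , drop = FALSE])
  tb <- tb / sqrt(rowSums(tb^2))
  list(points = pts, tangents = tg, tangent_bp = tb)
}

#' Bending angle of a helix segment
#'
#' The angle between the tangents of the two end base steps of the segment
#' along the central axis.
#'
#' @param frame a [HelixFrame-class].
#' @param start_bp first base pair of the segment (1-based).
#' @param n_bp segment length in base pairs.
#' @return bending angle in degrees.
#' @export
bendingAngle <- function(frame, start_bp = 1, n_bp = nBasePairs(frame)) {
  n <- nBasePairs(frame)
  if (start_bp < 1 || start_bp + n_bp - 1 > n)
    stop("segment out of bounds")
  if (n_bp < 3) stop("segment must span at least 3 base pairs")
  tg <- centralAxis(frame)$tangents
  t1 <- tg[start_bp, ]
  t2 <- tg[start_bp + n_bp - 2, ]
  .rad2deg(acos(min(1, max(-1, sum(t1 * t2)))))
}

#' Pool segment bending angles over a trajectory
#'
#' Every eligible window of \code{n_bp} consecutive base pairs (after
#' excluding \code{exclude_terminal} base pairs at each end) contributes one
#' bending angle per frame.  The segment contour length is computed from
#' the trajectory's own mean rise, scaled by the estimator-consistent
#' effective step count (n_bp - 2 - 8/9): the 3-bp-smoothed axis tangents
#' are chords averaging the local tangent over three steps, which shortens
#' the contour separating the two tangent estimates by exactly 8/9 of a
#' step beyond the end-step offset (a consequence of the linear smoothing
#' weights).  With this contour length the persistence-length fit is an
#' unbiased round trip against the discrete worm-like-chain generator.
#'
#' @param traj a [HelixTrajectory-class].
#' @param n_bp segment length in base pairs; default 13 for A-form and 11
#'   for B-form (similar contour lengths of ~3.3 nm).
#' @param exclude_terminal base pairs excluded at each end (default 3).
#' @return a [BendingEnsemble-class].
#' @export
collectSegments <- function(traj, n_bp = NULL, exclude_terminal = 3) {
  stopifnot(is(traj, "HelixTrajectory"))
  n <- nBasePairs(traj)
  m <- nFrames(traj)
  if (is.null(n_bp)) n_bp <- if (traj@form@name == "A") 13 else 11
  first <- exclude_terminal + 1
  last <- n - exclude_terminal
  starts <- seq_len(max(0, last - first + 1 - (n_bp - 1))) + first - 1
  if (!length(starts))
    stop("no eligible segment windows after terminal exclusion")

  # mean rise over all steps and frames
  stepvec <- traj@origin[-1, , , drop = FALSE] -
    traj@origin[-n, , , drop = FALSE]
  mean_rise <- mean(sqrt(apply(stepvec^2, c(1, 3), sum)))
  if (n_bp < 4) stop("segments must span at least 4 base pairs")
  Lc <- (n_bp - 2 - 8 / 9) * mean_rise

  ang <- matrix(NA_real_, m, length(starts))
  for (f in seq_len(m)) {
    fr <- getFrame(traj, f)
    tg <- centralAxis(fr)$tangents
    for (j in seq_along(starts)) {
      s <- starts[j]
      dd <- sum(tg[s, ] * tg[s + n_bp - 2, ])
      ang[f, j] <- acos(min(1, max(-1, dd)))
    }
  }
  new("BendingEnsemble", angles_deg = .rad2deg(as.numeric(ang)),
      segment_Lc = Lc, segment_bp = n_bp,
      meta = list(source = "collectSegments", n_windows = length(starts),
                  exclude_terminal = exclude_terminal,
                  mean_rise = mean_rise))
}

#' Histogram a bending-angle ensemble
#'
#' @param x a [BendingEnsemble-class] or numeric vector of angles in
#'   degrees.
#' @param bin_deg bin width in degrees (default 0.5).
#' @return an [AngleHistogram-class]; \code{density} integrates to 1 over
#'   the bins (per-degree units).
#' @export
angleHistogram <- function(x, bin_deg = 0.5) {
  a <- if (is(x, "BendingEnsemble")) x@angles_deg else as.numeric(x)
  if (any(a < 0 | a > 180)) stop("angles must lie in [0, 180] degrees")
  breaks <- seq(0, 180, by = bin_deg)
  if (breaks[length(breaks)] < 180) breaks <- c(breaks, 180)
  idx <- findInterval(a, breaks, rightmost.closed = TRUE, all.inside = TRUE)
  counts <- tabulate(idx, nbins = length(breaks) - 1)
  n <- length(a)
  dens <- if (n > 0) counts / (n * diff(breaks)) else counts * 0
  new("AngleHistogram", breaks_deg = breaks,
      mids_deg = (breaks[-1] + breaks[-length(breaks)]) / 2,
      counts = counts, density = dens, n = n)
}

# shared weighted quadratic fit: regress y on theta^2/(2 Lc) (theta rad)
# over bins passing the count and quantile filters
.fitQuadratic <- function(mids_deg, y, counts, Lc, min_count, q_max,
                          intercept, min_bins = 10) {
  keep <- is.finite(y) & counts >= min_count
  if (q_max < 1 && sum(counts) > 0) {
    cum <- cumsum(counts) / sum(counts)
    i_q <- which(cum >= q_max)[1]
    if (!is.na(i_q)) keep <- keep & seq_along(counts) <= i_q
  }
  if (sum(keep) < min_bins)
    stop("too few populated bins for a persistence-length fit")
  th <- .deg2rad(mids_deg[keep])
  xx <- th^2 / (2 * Lc)
  yy <- y[keep]
  ww <- counts[keep]
  fit <- if (intercept) stats::lm(yy ~ xx, weights = ww)
  else stats::lm(yy ~ xx - 1, weights = ww)
  cf <- suppressWarnings(summary(fit))$coefficients
  list(P = unname(cf["xx", "Estimate"]), se = unname(cf["xx", "Std. Error"]),
       n_bins = sum(keep), intercept = intercept,
       intercept_value = if (intercept) unname(cf["(Intercept)", "Estimate"])
                         else 0)
}

#' Persistence length from a bending-angle distribution
#'
#' Weighted linear regression of -ln(p(theta)/sin(theta)) on
#' theta^2/(2 Lc) (theta in radians) over the populated histogram bins; the
#' slope is the persistence length in nm.  Bins with fewer than
#' \code{min_count} counts or beyond the \code{q_max} angle quantile are
#' excluded to avoid log-of-small-count noise.  A free intercept (default)
#' absorbs the normalization constant of p(theta).
#'
#' @param hist an [AngleHistogram-class].
#' @param Lc segment contour length in nm.
#' @param min_count minimum counts for a bin to enter the fit.
#' @param q_max angle-quantile cutoff.
#' @param intercept logical; fit a free intercept.
#' @return list with P (nm), se, n_bins, intercept flag.
#' @export
fitPFromPdf <- function(hist, Lc, min_count = 20, q_max = 0.99,
                        intercept = TRUE) {
  stopifnot(is(hist, "AngleHistogram"))
  if (Lc <= 0) stop("Lc must be > 0")
  p_rad <- hist@density * (180 / pi)   # density per radian
  th <- .deg2rad(hist@mids_deg)
  y <- -log(p_rad / sin(th))
  y[!is.finite(y)] <- NA_real_
  .fitQuadratic(hist@mids_deg, y, hist@counts, Lc, min_count, q_max,
                intercept)
}

#' Bending-energy profile from a bending-angle distribution
#'
#' dE_bend(theta)/kBT = -ln(p(theta)/sin(theta)) on the bin centers,
#' shifted so the minimum over populated bins is zero.  Empty bins are
#' masked (NA), never interpolated.
#'
#' @param hist an [AngleHistogram-class].
#' @return data.frame with theta_deg, E_kBT, count.
#' @export
bendingEnergy <- function(hist) {
  stopifnot(is(hist, "AngleHistogram"))
  if (sum(hist@counts) == 0) stop("empty histogram")
  p_rad <- hist@density * (180 / pi)
  th <- .deg2rad(hist@mids_deg)
  E <- -log(p_rad / sin(th))
  E[hist@counts == 0 | !is.finite(E)] <- NA_real_
  E <- E - min(E, na.rm = TRUE)
  data.frame(theta_deg = hist@mids_deg, E_kBT = E, count = hist@counts)
}

#' Persistence length from a bending-energy profile
#'
#' Quadratic fit of the bending energy, dE_bend(theta)/kBT =
#' P theta^2 / (2 Lc): the same regression as [fitPFromPdf()] applied to an
#' energy profile, so the two routes agree exactly on identical grids.
#'
#' @param profile data.frame from [bendingEnergy()] (columns theta_deg,
#'   E_kBT and optionally count).
#' @param Lc segment contour length in nm.
#' @inheritParams fitPFromPdf
#' @return list with P (nm), se, n_bins, intercept flag.
#' @export
fitPFromEnergy <- function(profile, Lc, min_count = 20, q_max = 0.99,
                           intercept = TRUE) {
  if (Lc <= 0) stop("Lc must be > 0")
  counts <- if ("count" %in% names(profile)) profile$count
            else rep(min_count, nrow(profile))
  .fitQuadratic(profile$theta_deg, profile$E_kBT, counts, Lc, min_count,
                q_max, intercept)
}
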