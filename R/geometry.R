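# Base-pair and base-step geometry: inclination, simplified step
# parameters, axial groove widths, their fluctuations along a conformation
# and correlations with the bending angle.
#
# Axial groove widths: for each strand-1 phosphate, the strand-2 backbone
# is treated as a continuous helix (linear interpolation of axial position
# versus unwound azimuth); the minor width d is the axial gap to the
# strand-2 crossing on the minor-groove side of the base-pair frame and
# the major width D the gap on the other side, so that D + d equals the
# local pitch on an ideal helix.

#' Base-pair inclination
#'
#' Signed angle between the base-pair long axis and the plane perpendicular
#' to the local helical axis, in degrees.
#'
#' @param frame a [HelixFrame-class].
#' @param bp optional base-pair index; all base pairs when omitted.
#' @return inclination(s) in degrees.
#' @export
inclination <- function(frame, bp = NULL) {
  stopifnot(is(frame, "HelixFrame"))
  tb <- centralAxis(frame)$tangent_bp
  val <- .rad2deg(asin(pmin(1, pmax(-1, rowSums(frame@lng * tb)))))
  if (is.null(bp)) val else val[bp]
}

# unwound azimuths and axial coordinates of both strands' phosphates
.phosphateHelixCoords <- function(frame) {
  ax <- centralAxis(frame)
  A <- ax$points; tb <- ax$tangent_bp
  n <- nrow(A)
  seglen <- sqrt(rowSums((A[-1, , drop = FALSE] - A[-n, , drop = FALSE])^2))
  s_axis <- c(0, cumsum(seglen))
  lin <- .inplaneLong(frame)

  azim <- function(p) {
    v <- p - A
    v <- v - tb * rowSums(v * tb)
    atan2(rowSums(v * lin), rowSums(v * frame@shrt))
  }
  sco <- function(p) s_axis + rowSums((p - A) * tb)

  # cumulative frame twist about the local tangent
  tw <- numeric(n - 1)
  for (k in seq_len(n - 1)) {
    s1 <- frame@shrt[k, ]; s2 <- frame@shrt[k + 1, ]
    tmid <- .unit(tb[k, ] + tb[k + 1, ])
    s1p <- .unit(s1 - tmid * sum(s1 * tmid))
    s2p <- .unit(s2 - tmid * sum(s2 * tmid))
    cr <- .rowcross(rbind(s1p), rbind(s2p))[1, ]
    tw[k] <- atan2(sum(cr * tmid), sum(s1p * s2p))
  }
  cumtw <- c(0, cumsum(tw))

  a1 <- azim(frame@p1); a2 <- azim(frame@p2)
  # unwrap the per-bp azimuth against the accumulated twist so the total
  # (twist + local azimuth) is continuous along each strand
  unwrapAgainst <- function(a) {
    phi <- a + cumtw
    phi[1] + c(0, cumsum(((diff(phi) + pi) %% (2 * pi)) - pi))
  }
  list(s1 = sco(frame@p1), s2 = sco(frame@p2),
       phi1 = unwrapAgainst(a1), phi2 = unwrapAgainst(a2),
       mean_twist = mean(abs(tw)), s_axis = s_axis)
}

#' Axial groove widths along a conformation
#'
#' For each strand-1 phosphate the axial gaps to the strand-2 backbone on
#' the minor- and major-groove sides.  On an ideal helix the total width
#' D + d equals the pitch.  Terminal phosphates lacking a crossing on one
#' side are dropped; a helix shorter than one full turn yields a truncated
#' series with a warning.
#'
#' @param frame a [HelixFrame-class].
#' @return data.frame with bp, d (minor, nm), D (major, nm), total (nm).
#' @export
axialGrooveWidths <- function(frame) {
  stopifnot(is(frame, "HelixFrame"))
  hc <- .phosphateHelixCoords(frame)
  n <- length(hc$s1)
  # strand-2 helix: axial position as a function of unwound azimuth
  ord <- order(hc$phi2)
  phi2 <- hc$phi2[ord]; s2 <- hc$s2[ord]
  if (any(diff(phi2) <= 0)) {
    keep <- c(TRUE, diff(phi2) > 1e-9)
    phi2 <- phi2[keep]; s2 <- s2[keep]
  }
  res <- data.frame(bp = integer(), d = numeric(), D = numeric(),
                    total = numeric())
  for (i in seq_len(n)) {
    # strand-2 crossings of this phosphate's azimuth (mod 2 pi)
    kmin <- ceiling((phi2[1] - hc$phi1[i]) / (2 * pi))
    kmax <- floor((phi2[length(phi2)] - hc$phi1[i]) / (2 * pi))
    if (kmax < kmin) next
    targets <- hc$phi1[i] + 2 * pi * seq(kmin, kmax)
    s_cross <- stats::approx(phi2, s2, xout = targets, ties = "ordered")$y
    below <- s_cross[s_cross < hc$s1[i]]
    above <- s_cross[s_cross >= hc$s1[i]]
    if (!length(below) || !length(above)) next
    gap_dn <- hc$s1[i] - max(below)
    gap_up <- min(above) - hc$s1[i]
    res <- rbind(res, data.frame(bp = i, d = gap_dn, D = gap_up,
                                 total = gap_dn + gap_up))
  }
  if (!nrow(res))
    warning("helix shorter than one full turn: no groove widths measurable")
  res
}

#' Simplified base-pair and base-step helical parameters
#'
#' Computes the six rigid-body step parameters (shift, slide, rise, tilt,
#' roll, twist) from consecutive base-pair triads using a symmetric
#' mid-frame convention, plus the per-base-pair inclination.  These follow
#' the standard Cartesian frame definitions in a simplified coarse-site
#' form (no full Curves+/3DNA re-implementation).
#'
#' @param frame a [HelixFrame-class].
#' @return list with \code{step} (data.frame of the six step parameters,
#'   angles in degrees, translations in nm) and \code{bp} (data.frame with
#'   inclination in degrees).
#' @export
helicalParameters <- function(frame) {
  stopifnot(is(frame, "HelixFrame"))
  n <- nBasePairs(frame)
  out <- matrix(0, n - 1, 6,
                dimnames = list(NULL, c("shift", "slide", "rise",
                                        "tilt", "roll", "twist")))
  for (k in seq_len(n - 1)) {
    T1 <- cbind(frame@shrt[k, ], frame@lng[k, ], frame@nrm[k, ])
    T2 <- cbind(frame@shrt[k + 1, ], frame@lng[k + 1, ], frame@nrm[k + 1, ])
    Rrel <- t(T1) %*% T2
    ang <- acos(min(1, max(-1, (sum(diag(Rrel)) - 1) / 2)))
    if (ang < 1e-12) rho <- c(0, 0, 0)
    else {
      axis <- c(Rrel[3, 2] - Rrel[2, 3], Rrel[1, 3] - Rrel[3, 1],
                Rrel[2, 1] - Rrel[1, 2]) / (2 * sin(ang))
      rho <- axis * ang
    }
    # mid-frame: average the triads (adequate for small steps)
    Tm <- (T1 + T2) / 2
    Tm <- apply(Tm, 2, .unit)
    rho_lab <- T1 %*% rho          # rotation vector in lab coordinates
    d <- frame@origin[k + 1, ] - frame@origin[k, ]
    out[k, c("tilt", "roll", "twist")] <-
      .rad2deg(as.numeric(t(Tm) %*% rho_lab))
    out[k, c("shift", "slide", "rise")] <- as.numeric(t(Tm) %*% d)
  }
  list(step = data.frame(step = seq_len(n - 1), out),
       bp = data.frame(bp = seq_len(n), inclination = inclination(frame)))
}

#' Per-frame fluctuation of a structural observable
#'
#' The standard deviation of the observable along the conformation,
#' computed per frame: for \code{total_groove_width} the SD of D + d over
#' positions, normalized per unit contour length (per nm of axis); for
#' \code{inclination} the SD of the base-pair inclination in degrees.
#' Trajectory mean and block standard deviations are reported.
#'
#' @param traj a [HelixTrajectory-class].
#' @param observable "total_groove_width" or "inclination".
#' @param n_blocks trajectory blocks for the error estimate.
#' @return list with \code{per_frame} (frame, sd), \code{mean} and
#'   \code{block_sd}.
#' @export
fluctuationProfile <- function(traj,
                               observable = c("total_groove_width",
                                              "inclination"),
                               n_blocks = 4) {
  stopifnot(is(traj, "HelixTrajectory"))
  observable <- match.arg(observable)
  m <- nFrames(traj)
  if (nBasePairs(traj) < 3) stop("frames must span at least 2 steps")
  v <- numeric(m)
  for (f in seq_len(m)) {
    fr <- getFrame(traj, f)
    if (observable == "inclination") {
      v[f] <- stats::sd(inclination(fr))
    } else {
      gw <- axialGrooveWidths(fr)
      if (nrow(gw) < 2) { v[f] <- NA_real_; next }
      ax <- centralAxis(fr)$points
      Lc <- sum(sqrt(rowSums((ax[-1, , drop = FALSE] -
                              ax[-nrow(ax), , drop = FALSE])^2)))
      v[f] <- stats::sd(gw$total) / Lc
    }
  }
  blk <- cut(seq_len(m), breaks = n_blocks, labels = FALSE)
  bm <- tapply(v, blk, mean, na.rm = TRUE)
  list(per_frame = data.frame(frame = seq_len(m), sd = v),
       mean = mean(v, na.rm = TRUE),
       block_sd = if (m >= n_blocks) stats::sd(bm) else NA_real_)
}

#' Correlate structural fluctuations with the bending angle
#'
#' Computes, per frame, the whole-molecule bending angle (terminal base
#' pairs excluded) and a set of structural observables, and reports the
#' Pearson correlation coefficient of each with the angle: the fluctuation
#' (SD along the conformation) of the minor, major and total axial groove
#' widths and of the base-pair inclination, plus the per-frame mean and
#' fluctuation of each base-step parameter (the weak-correlation screen).
#'
#' @param traj a [HelixTrajectory-class].
#' @param exclude_terminal base pairs excluded at each end for the angle.
#' @param observables subset of c("grooves", "inclination", "step_params")
#'   to compute.
#' @return data.frame with observable, r, n; constant series give NA.
#' @export
correlateWithBend <- function(traj, exclude_terminal = 3,
                              observables = c("grooves", "inclination",
                                              "step_params")) {
  stopifnot(is(traj, "HelixTrajectory"))
  m <- nFrames(traj)
  n <- nBasePairs(traj)
  theta <- numeric(m)
  vals <- list()
  addCol <- function(name) vals[[name]] <<- rep(NA_real_, m)
  if ("grooves" %in% observables)
    for (nm in c("sd_d", "sd_D", "sd_total")) addCol(nm)
  if ("inclination" %in% observables) addCol("sd_inclination")
  if ("step_params" %in% observables)
    for (p in c("shift", "slide", "rise", "tilt", "roll", "twist"))
      for (suf in c("mean", "sd")) addCol(paste0(p, "_", suf))

  for (f in seq_len(m)) {
    fr <- getFrame(traj, f)
    theta[f] <- bendingAngle(fr, exclude_terminal + 1,
                             n - 2 * exclude_terminal)
    if ("grooves" %in% observables) {
      gw <- axialGrooveWidths(fr)
      if (nrow(gw) >= 2) {
        vals$sd_d[f] <- stats::sd(gw$d)
        vals$sd_D[f] <- stats::sd(gw$D)
        vals$sd_total[f] <- stats::sd(gw$total)
      }
    }
    if ("inclination" %in% observables)
      vals$sd_inclination[f] <- stats::sd(inclination(fr))
    if ("step_params" %in% observables) {
      hp <- helicalParameters(fr)$step
      for (p in c("shift", "slide", "rise", "tilt", "roll", "twist")) {
        vals[[paste0(p, "_mean")]][f] <- mean(hp[[p]])
        vals[[paste0(p, "_sd")]][f] <- stats::sd(hp[[p]])
      }
    }
  }
  res <- do.call(rbind, lapply(names(vals), function(nm) {
    y <- vals[[nm]]
    ok <- is.finite(y)
    r <- if (sum(ok) > 2 && stats::sd(y[ok]) > 0 && stats::sd(theta[ok]) > 0)
      stats::cor(theta[ok], y[ok]) else NA_real_
    data.frame(observable = nm, r = r, n = sum(ok))
  }))
  res
}
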