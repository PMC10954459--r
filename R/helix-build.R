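# Construction of idealized A-form / B-form duplexes and controlled bending.
#
# Geometry conventions: base-pair origins start on the z axis; the base-pair
# short axis points toward the major-groove bisector and the long axis spans
# the pair; phosphates sit at the helical radius at fixed azimuths in the
# local (short, long) basis, so that the counter-clockwise arc from the
# strand-1 phosphate to the strand-2 phosphate spans the minor groove.

.deg2rad <- function(x) x * pi / 180
.rad2deg <- function(x) x * 180 / pi

.vnorm <- function(v) sqrt(sum(v^2))
.unit <- function(v) v / .vnorm(v)

# row-wise cross product of two n x 3 matrices
.rowcross <- function(a, b) {
  cbind(a[, 2] * b[, 3] - a[, 3] * b[, 2],
        a[, 3] * b[, 1] - a[, 1] * b[, 3],
        a[, 1] * b[, 2] - a[, 2] * b[, 1])
}

# Rodrigues rotation of the rows of m about unit axis a by angle (rad).
# a may be one axis (length 3) for all rows or an n x 3 matrix of per-row
# axes; angle may be scalar or per-row.
.rotateRows <- function(m, a, angle) {
  if (is.null(dim(a))) a <- matrix(a, nrow = nrow(m), ncol = 3, byrow = TRUE)
  ca <- cos(angle); sa <- sin(angle)
  adotm <- rowSums(a * m)
  m * ca + .rowcross(a, m) * sa + a * (adotm * (1 - ca))
}

# 3x3 rotation matrix about unit axis a by angle (rad)
.rotMat <- function(a, angle) {
  a <- .unit(a)
  ca <- cos(angle); sa <- sin(angle)
  K <- matrix(c(0, a[3], -a[2], -a[3], 0, a[1], a[2], -a[1], 0), 3, 3)
  diag(3) * ca + sa * K + (1 - ca) * outer(a, a)
}

#' Canonical A-form and B-form helix geometries
#'
#' Fixture constants for the two duplex forms.  The rise values (0.28 nm/bp
#' A-form, 0.34 nm/bp B-form) and the 1.0 nm phosphate-helix radius follow
#' the measured duplex geometry; twist, resting inclination and axial groove
#' fractions are standard fiber-diffraction values used here purely as
#' construction constants for synthetic conformations.
#'
#' @param name "A" (dsRNA) or "B" (dsDNA).
#' @return a [HelixForm-class].
#' @examples
#' helixForm("B")
#' @export
helixForm <- function(name = c("A", "B")) {
  name <- match.arg(name)
  if (name == "A") {
    new("HelixForm", name = "A", rise_per_bp = 0.28, twist_per_bp = 32.7,
        inclination0 = 17, helical_radius = 1.0,
        groove_fractions = c(major = 0.25, minor = 0.75))
  } else {
    new("HelixForm", name = "B", rise_per_bp = 0.34, twist_per_bp = 34.3,
        inclination0 = -1, helical_radius = 1.0,
        groove_fractions = c(major = 0.65, minor = 0.35))
  }
}

# phosphate azimuths (rad) in the local (short, long) basis: the CCW arc
# from strand 1 to strand 2 spans the minor groove, whose bisector is
# opposite the short axis (the short axis points at the major groove).
.phosphateAzimuths <- function(form) {
  fm <- form@groove_fractions[["minor"]]
  c(a1 = pi - pi * fm, a2 = pi + pi * fm)
}

#' Build an ideal straight helix
#'
#' Constructs a straight idealized duplex: base-pair origins on a straight
#' axis spaced by the form's rise, base-pair triads twisted by the form's
#' twist per step and inclined by its resting inclination, phosphates on two
#' helical strands at the form's radius.
#'
#' @param form a [HelixForm-class] (or "A"/"B" shorthand).
#' @param n_bp number of base pairs (>= 4).
#' @param phosphate_charge charge per phosphate in e; use 0 for the
#'   electrically neutral construct.
#' @return a [HelixFrame-class].
#' @examples
#' fr <- makeIdealHelix("B", 20)
#' nBasePairs(fr)
#' @export
makeIdealHelix <- function(form, n_bp, phosphate_charge = -1) {
  if (is.character(form)) form <- helixForm(form)
  stopifnot(is(form, "HelixForm"))
  if (n_bp < 4) stop("n_bp must be at least 4")
  h <- form@rise_per_bp
  Om <- .deg2rad(form@twist_per_bp)
  eta <- .deg2rad(form@inclination0)
  R <- form@helical_radius
  az <- .phosphateAzimuths(form)

  i <- seq_len(n_bp) - 1
  origin <- cbind(0, 0, i * h)
  phi <- i * Om                      # twist of the local frame about z
  # axis-frame vectors: tangent z, short axis s, in-plane long axis l0
  s <- cbind(cos(phi), sin(phi), 0)
  l0 <- cbind(-sin(phi), cos(phi), 0)        # z x s
  zhat <- cbind(0, 0, rep(1, n_bp))
  # base-pair triad with inclination: rotate l0 about s by eta
  lng <- l0 * cos(eta) + zhat * sin(eta)
  nrm <- zhat * cos(eta) - l0 * sin(eta)     # s x lng
  # phosphates at fixed azimuths in the (s, l0) basis (un-inclined plane)
  p1 <- origin + R * (cos(az["a1"]) * s + sin(az["a1"]) * l0)
  p2 <- origin + R * (cos(az["a2"]) * s + sin(az["a2"]) * l0)

  new("HelixFrame", p1 = p1, p2 = p2, origin = origin,
      nrm = nrm, lng = lng, shrt = s, form = form,
      phosphate_charge = phosphate_charge)
}

# indices of base pairs strictly downstream of step k (step k joins bp k and
# k+1, 1-based)
.downstreamOf <- function(k, n_bp) seq(k + 1, n_bp)

#' Bend a helix toward the major or minor groove
#'
#' Applies a controlled bend of total angle \code{theta} so that the tangents
#' of the two end base steps subtend that angle.  The bend is distributed as
#' a smooth arc over \code{window} consecutive steps centred on
#' \code{pivot_step} (use \code{window = 1} for a single kink).  Spreading
#' the rotation keeps strand bond geometry nearly rigid: for theta <= 30 deg
#' and the default window, inter-phosphate distances change by well under
#' 1 percent.
#'
#' Bending toward the major groove additionally rotates the base pairs in
#' the bend window about their short axes by \code{+incl_coupling * theta}
#' (toward the minor groove by the negative), planting the geometric
#' coupling by which bends toward the major and minor grooves raise and
#' lower base-pair inclination.
#'
#' @param frame a [HelixFrame-class].
#' @param theta bend angle in degrees, in \[0, 90\].
#' @param direction "major" or "minor": groove toward which the helix bends.
#' @param pivot_step base step (1-based, joining bp \code{pivot_step} and
#'   \code{pivot_step + 1}) at the centre of the bend.
#' @param window number of steps over which the bend is distributed.
#' @param incl_coupling inclination-coupling constant (degrees of extra
#'   inclination per degree of bend, applied within the window).
#' @return the bent [HelixFrame-class].
#' @export
bendHelix <- function(frame, theta, direction = c("major", "minor"),
                      pivot_step = NULL, window = 9, incl_coupling = 0.25) {
  stopifnot(is(frame, "HelixFrame"))
  direction <- match.arg(direction)
  if (theta < 0 || theta > 90) stop("theta must lie in [0, 90] degrees")
  n <- nBasePairs(frame)
  if (is.null(pivot_step)) pivot_step <- floor(n / 2)
  if (pivot_step < 1 || pivot_step >= n) stop("pivot_step out of range")
  if (theta == 0) return(frame)

  # bend direction: groove bisector at the pivot, in the plane normal to the
  # local tangent; rotation axis a = t x u tilts the downstream tangent
  # toward u
  tvec <- .unit(frame@origin[pivot_step + 1, ] - frame@origin[pivot_step, ])
  u <- frame@shrt[pivot_step, ]
  u <- .unit(u - tvec * sum(u * tvec))
  if (direction == "minor") u <- -u
  a <- .unit(.rowcross(rbind(tvec), rbind(u))[1, ])

  # steps carrying the arc, clipped to the interior
  half <- (window - 1) / 2
  ks <- seq(ceiling(pivot_step - half), floor(pivot_step + half))
  ks <- ks[ks >= 1 & ks < n]
  dphi <- .deg2rad(theta) / length(ks)

  p1 <- frame@p1; p2 <- frame@p2; origin <- frame@origin
  nrm <- frame@nrm; lng <- frame@lng; shrt <- frame@shrt
  Rm <- .rotMat(a, dphi)
  for (k in ks) {
    idx <- .downstreamOf(k, n)
    ctr <- (origin[k, ] + origin[k + 1, ]) / 2
    b1_len <- .vnorm(p1[k + 1, ] - p1[k, ])
    b2_len <- .vnorm(p2[k + 1, ] - p2[k, ])
    rotPts <- function(m) {
      sweep(sweep(m[idx, , drop = FALSE], 2, ctr) %*% t(Rm), 2, ctr, "+")
    }
    rotVec <- function(m) m[idx, , drop = FALSE] %*% t(Rm)
    p1[idx, ] <- rotPts(p1); p2[idx, ] <- rotPts(p2)
    origin[idx, ] <- rotPts(origin)
    nrm[idx, ] <- rotVec(nrm); lng[idx, ] <- rotVec(lng)
    shrt[idx, ] <- rotVec(shrt)
    # small downstream translation restoring the strand bond lengths
    # across the hinge (an inextensible-backbone correction)
    b1 <- p1[k + 1, ] - p1[k, ]; b2 <- p2[k + 1, ] - p2[k, ]
    e <- c(b1_len - .vnorm(b1), b2_len - .vnorm(b2))
    bh1 <- .unit(b1); bh2 <- .unit(b2)
    g <- sum(bh1 * bh2)
    G <- rbind(c(1, g), c(g, 1))
    if (abs(det(G)) > 1e-8) {
      al <- solve(G, e)
      tr <- al[1] * bh1 + al[2] * bh2
      p1[idx, ] <- sweep(p1[idx, , drop = FALSE], 2, tr, "+")
      p2[idx, ] <- sweep(p2[idx, , drop = FALSE], 2, tr, "+")
      origin[idx, ] <- sweep(origin[idx, , drop = FALSE], 2, tr, "+")
    }
  }
  frame@p1 <- p1; frame@p2 <- p2; frame@origin <- origin
  frame@nrm <- nrm; frame@lng <- lng; frame@shrt <- shrt

  # planted inclination coupling within the bend window
  if (incl_coupling != 0) {
    bps <- unique(c(ks, ks + 1))
    delta <- .deg2rad(incl_coupling * theta) *
      (if (direction == "major") 1 else -1)
    for (b in bps) {
      Rb <- .rotMat(frame@shrt[b, ], delta)
      frame@lng[b, ] <- as.numeric(Rb %*% frame@lng[b, ])
      frame@nrm[b, ] <- as.numeric(Rb %*% frame@nrm[b, ])
    }
  }
  frame
}

#' Apply a rigid-body transform to a frame
#'
#' Utility for invariance checks: rotates all coordinates and triad vectors
#' by \code{R} and then translates positions by \code{t}.
#'
#' @param frame a [HelixFrame-class].
#' @param R 3x3 rotation matrix.
#' @param t length-3 translation in nm.
#' @return the transformed [HelixFrame-class].
#' @export
transformFrame <- function(frame, R = diag(3), t = c(0, 0, 0)) {
  stopifnot(is(frame, "HelixFrame"))
  mv <- function(m) sweep(m %*% t(R), 2, t, "+")
  rv <- function(m) m %*% t(R)
  new("HelixFrame",
      p1 = mv(frame@p1), p2 = mv(frame@p2), origin = mv(frame@origin),
      nrm = rv(frame@nrm), lng = rv(frame@lng), shrt = rv(frame@shrt),
      form = frame@form, phosphate_charge = frame@phosphate_charge)
}
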