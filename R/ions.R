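# Classification of ions into binding shells and derived statistics.
#
# Internal (groove) binding: perpendicular distance to the local helical
# axis <= 8.5 A (the ~10 A helical radius minus the ~1.5 A phosphate
# radius) and azimuth inside the major- or minor-groove sector of the local
# base-pair frame.  External binding: not internal, and within 6 A of a
# phosphate atom (the second shell of the cation distribution around
# phosphates).  Groove labels take precedence over the external label.

#' Classify ions into binding shells
#'
#' @param frame a [HelixFrame-class].
#' @param ions data.frame with columns x, y, z (nm) and optionally species,
#'   charge.
#' @param cutoff_ext external-shell cutoff: maximum distance to a phosphate
#'   in nm (default 0.6).
#' @param cutoff_helical internal-shell cutoff: maximum perpendicular
#'   distance to the local helical axis in nm (default 0.85).
#' @return the input data.frame with added columns \code{shell} (one of
#'   "internal_major", "internal_minor", "external", "bulk"), \code{r_axis}
#'   (axis distance, nm) and \code{d_phos} (distance to the nearest
#'   phosphate, nm).  Every ion receives exactly one label.
#' @export
classifyIons <- function(frame, ions, cutoff_ext = 0.6,
                         cutoff_helical = 0.85) {
  stopifnot(is(frame, "HelixFrame"))
  q <- nrow(ions)
  if (q == 0) {
    ions$shell <- character(0); ions$r_axis <- numeric(0)
    ions$d_phos <- numeric(0)
    return(ions)
  }
  ax <- centralAxis(frame)
  A <- ax$points; tb <- ax$tangent_bp
  n <- nrow(A)
  h <- frame@form@rise_per_bp
  lin <- .inplaneLong(frame)
  im <- as.matrix(ions[, c("x", "y", "z")])

  # nearest axis point per ion
  D2 <- outer(rowSums(im^2), rep(1, n)) +
    outer(rep(1, q), rowSums(A^2)) - 2 * im %*% t(A)
  kstar <- max.col(-D2, ties.method = "first")

  v <- im - A[kstar, , drop = FALSE]
  tk <- tb[kstar, , drop = FALSE]
  axial <- rowSums(v * tk)
  perp2 <- pmax(0, rowSums(v^2) - axial^2)
  r_axis <- sqrt(perp2)

  # azimuth of the ion and of the two phosphates in the local frame
  vperp <- v - tk * axial
  sk <- frame@shrt[kstar, , drop = FALSE]
  lk <- lin[kstar, , drop = FALSE]
  a_ion <- atan2(rowSums(vperp * lk), rowSums(vperp * sk)) %% (2 * pi)
  w1 <- frame@p1[kstar, , drop = FALSE] - A[kstar, , drop = FALSE]
  w2 <- frame@p2[kstar, , drop = FALSE] - A[kstar, , drop = FALSE]
  w1 <- w1 - tk * rowSums(w1 * tk); w2 <- w2 - tk * rowSums(w2 * tk)
  a1 <- atan2(rowSums(w1 * lk), rowSums(w1 * sk)) %% (2 * pi)
  a2 <- atan2(rowSums(w2 * lk), rowSums(w2 * sk)) %% (2 * pi)
  arc_to_ion <- (a_ion - a1) %% (2 * pi)
  arc_minor <- (a2 - a1) %% (2 * pi)
  in_minor <- arc_to_ion <= arc_minor

  # inside the rod axially (no caps beyond the terminal base pairs)
  inside_rod <- abs(axial) <= h &
    !(kstar == 1 & axial < -h / 2) & !(kstar == n & axial > h / 2)

  # distance to the nearest phosphate
  Pm <- rbind(frame@p1, frame@p2)
  DP2 <- outer(rowSums(im^2), rep(1, nrow(Pm))) +
    outer(rep(1, q), rowSums(Pm^2)) - 2 * im %*% t(Pm)
  d_phos <- sqrt(pmax(0, apply(DP2, 1, min)))

  internal <- r_axis <= cutoff_helical & inside_rod
  shell <- ifelse(internal, ifelse(in_minor, "internal_minor",
                                   "internal_major"),
                  ifelse(d_phos <= cutoff_ext, "external", "bulk"))
  ions$shell <- shell
  ions$r_axis <- r_axis
  ions$d_phos <- d_phos
  ions
}

#' Per-nucleotide charge fractions of binding ions
#'
#' For every frame, ions are classified into shells and the signed charge
#' (cations minus anions) per nucleotide is accumulated per shell; the
#' trajectory average is reported with the standard deviation over
#' \code{n_blocks} equal trajectory intervals.
#'
#' @param traj a [HelixTrajectory-class] carrying ion records.
#' @param cutoff_ext,cutoff_helical shell cutoffs in nm.
#' @param n_blocks number of equal trajectory blocks for the error estimate.
#' @return list with \code{per_frame} (data.frame of per-frame fractions)
#'   and \code{summary} (shell, mean, sd over blocks); the "total" row sums
#'   the three bound shells.
#' @export
chargeFractions <- function(traj, cutoff_ext = 0.6, cutoff_helical = 0.85,
                            n_blocks = 4) {
  stopifnot(is(traj, "HelixTrajectory"))
  m <- nFrames(traj)
  n_nt <- 2 * nBasePairs(traj)
  if (n_nt == 0) stop("trajectory has no nucleotides")
  shells <- c("external", "internal_major", "internal_minor", "bulk")
  out <- matrix(0, m, length(shells), dimnames = list(NULL, shells))
  for (f in seq_len(m)) {
    io <- frameIons(traj, f)
    if (!nrow(io)) next
    cl <- classifyIons(getFrame(traj, f), io, cutoff_ext, cutoff_helical)
    for (s in shells)
      out[f, s] <- sum(cl$charge[cl$shell == s]) / n_nt
  }
  pf <- data.frame(frame = seq_len(m), out,
                   total = rowSums(out[, 1:3, drop = FALSE]))
  blk <- cut(seq_len(m), breaks = n_blocks, labels = FALSE)
  summ <- do.call(rbind, lapply(c(shells[1:3], "total"), function(s) {
    v <- pf[[s]]
    bm <- tapply(v, blk, mean)
    data.frame(shell = s, mean = mean(v),
               sd = if (m >= n_blocks) stats::sd(bm) else NA_real_)
  }))
  list(per_frame = pf, summary = summ)
}

#' Radial concentration profile around the helical axis
#'
#' Counts ions of one species in cylindrical shells around the central
#' axis (shell volume corrected) and converts to mM.  Radii beyond the
#' largest cylinder inscribed in the simulation box are truncated with a
#' warning, since shell volumes there are no longer fully inside the box.
#'
#' @param traj a [HelixTrajectory-class] (>= 10 frames).
#' @param species ion species to count (e.g. "Na").
#' @param dr radial bin width in nm.
#' @param r_max largest radius in nm; default the inscribed lateral radius
#'   of the box.
#' @return data.frame with r_mid (nm), conc_mM, count.
#' @export
radialConcentrationProfile <- function(traj, species = "Na", dr = 0.25,
                                       r_max = NULL) {
  stopifnot(is(traj, "HelixTrajectory"))
  m <- nFrames(traj)
  if (m < 10) stop("need at least 10 frames for a concentration profile")
  margin <- traj@config$box_margin
  if (is.null(margin)) margin <- 3
  r_lim <- traj@form@helical_radius + margin
  if (is.null(r_max)) r_max <- r_lim
  if (r_max > r_lim + 1e-9) {
    warning("r grid exceeds the box; truncated at ", signif(r_lim, 3), " nm")
    r_max <- r_lim
  }
  edges <- seq(0, r_max, by = dr)
  if (edges[length(edges)] < r_max) edges <- c(edges, r_max)
  nb <- length(edges) - 1
  counts <- numeric(nb)
  span_tot <- 0
  for (f in seq_len(m)) {
    fr <- getFrame(traj, f)
    ax <- centralAxis(fr)
    L <- sum(sqrt(rowSums((ax$points[-1, , drop = FALSE] -
                           ax$points[-nrow(ax$points), , drop = FALSE])^2)))
    span_tot <- span_tot + L
    io <- frameIons(traj, f)
    io <- io[io$species == species, , drop = FALSE]
    if (!nrow(io)) next
    cl <- classifyIons(fr, io)
    # keep ions whose axial position projects inside the helix span
    A <- ax$points; tb <- ax$tangent_bp
    im <- as.matrix(io[, c("x", "y", "z")])
    D2 <- outer(rowSums(im^2), rep(1, nrow(A))) +
      outer(rep(1, nrow(im)), rowSums(A^2)) - 2 * im %*% t(A)
    k <- max.col(-D2, ties.method = "first")
    inside <- k > 1 & k < nrow(A)
    r <- cl$r_axis[inside]
    idx <- findInterval(r, edges, rightmost.closed = TRUE)
    idx <- idx[idx >= 1 & idx <= nb]
    counts <- counts + tabulate(idx, nbins = nb)
  }
  L_mean <- span_tot / m
  vol <- pi * (edges[-1]^2 - edges[-(nb + 1)]^2) * L_mean
  conc <- counts / m / vol / .mM_per_nm3
  data.frame(r_mid = (edges[-1] + edges[-(nb + 1)]) / 2,
             conc_mM = conc, count = counts)
}

#' Shell charge fractions as a function of bending angle
#'
#' Computes, per frame, the whole-molecule bending angle (terminal base
#' pairs excluded) and the per-shell charge fractions, then bins the
#' fractions by angle and reports the Pearson correlation of each bound
#' fraction with the bending angle.
#'
#' @param traj a [HelixTrajectory-class] with ions.
#' @param bin_deg angle bin width in degrees.
#' @param exclude_terminal base pairs excluded at each end for the angle.
#' @param n_blocks trajectory blocks for binned standard deviations.
#' @param cutoff_ext,cutoff_helical shell cutoffs in nm.
#' @return list with \code{per_frame} (theta_deg + fractions),
#'   \code{table} (angle-binned means with block sds) and \code{pearson}
#'   (named correlations for external, internal, total).
#' @export
bendVsBinding <- function(traj, bin_deg = 5, exclude_terminal = 3,
                          n_blocks = 4, cutoff_ext = 0.6,
                          cutoff_helical = 0.85) {
  stopifnot(is(traj, "HelixTrajectory"))
  m <- nFrames(traj)
  n <- nBasePairs(traj)
  cf <- chargeFractions(traj, cutoff_ext, cutoff_helical, n_blocks)$per_frame
  theta <- numeric(m)
  for (f in seq_len(m))
    theta[f] <- bendingAngle(getFrame(traj, f), exclude_terminal + 1,
                             n - 2 * exclude_terminal)
  pf <- data.frame(theta_deg = theta,
                   external = cf$external,
                   internal = cf$internal_major + cf$internal_minor,
                   total = cf$total)
  bins <- floor(theta / bin_deg)
  populated <- length(unique(bins))
  if (populated < 3)
    stop("insufficient data: fewer than 3 populated angle bins")
  blk <- cut(seq_len(m), breaks = n_blocks, labels = FALSE)
  tab <- do.call(rbind, lapply(sort(unique(bins)), function(b) {
    sel <- bins == b
    bm <- tapply(pf$external[sel], blk[sel], mean)
    data.frame(theta_mid = (b + 0.5) * bin_deg,
               mean_external = mean(pf$external[sel]),
               mean_internal = mean(pf$internal[sel]),
               mean_total = mean(pf$total[sel]),
               sd_external = if (sum(sel) > 1) stats::sd(bm, na.rm = TRUE)
                             else NA_real_,
               n = sum(sel))
  }))
  safeCor <- function(y) {
    if (stats::sd(y) == 0 || stats::sd(theta) == 0) return(NA_real_)
    stats::cor(theta, y)
  }
  pearson <- c(external = safeCor(pf$external),
               internal = safeCor(pf$internal),
               total = safeCor(pf$total))
  list(per_frame = pf, table = tab, pearson = pearson)
}
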