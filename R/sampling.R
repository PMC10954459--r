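# Seeded synthetic-data generators: WLC angle ensembles, noisy
# force-extension traces, discrete worm-like-chain trajectories with ion
# atmospheres.  These stand in for the magnetic-tweezers instrument and the
# MD engine; every generator is a pure function of its configuration.

# draw n bending angles (radians) from p(theta) ~ sin(theta)
# exp(-P theta^2 / 2 Lc) on [0, pi] by numerical inverse-CDF on a grid
.sampleTheta <- function(n, P, Lc, grid_n = 4096) {
  theta_max <- min(pi, 8 * sqrt(2 * Lc / P))
  th <- seq(0, theta_max, length.out = grid_n)
  f <- sin(th) * exp(-P * th^2 / (2 * Lc))
  cdf <- cumsum(c(0, (f[-1] + f[-grid_n]) / 2 * diff(th)))
  cdf <- cdf / cdf[grid_n]
  u <- stats::runif(n)
  stats::approx(cdf, th, xout = u, ties = "ordered")$y
}

#' Sample a worm-like-chain bending-angle ensemble
#'
#' Draws i.i.d. bending angles from the WLC segment-angle density
#' p(theta) proportional to sin(theta) * exp(-P theta^2 / 2 Lc) on
#' \[0, pi\], by numerical inversion of the CDF tabulated on a fine grid.
#'
#' @param P persistence length in nm (> 0).
#' @param Lc segment contour length in nm (> 0).
#' @param n number of angles (>= 1).
#' @param seed optional integer seed; identical seeds give identical
#'   ensembles and the caller's RNG state is left untouched.
#' @param grid_n inverse-CDF grid resolution.
#' @return a [BendingEnsemble-class] with angles in degrees.
#' @examples
#' ens <- sampleWlcAngles(39, 3.3, 1000, seed = 1)
#' mean(angles(ens))
#' @export
sampleWlcAngles <- function(P, Lc, n, seed = NULL, grid_n = 4096) {
  if (P <= 0 || Lc <= 0) stop("P and Lc must be > 0")
  if (n < 1) stop("n must be >= 1")
  th <- withSeed(seed, .sampleTheta(n, P, Lc, grid_n))
  new("BendingEnsemble", angles_deg = .rad2deg(th), segment_Lc = Lc,
      segment_bp = NA_real_,
      meta = list(source = "sampleWlcAngles", P = P, seed = seed))
}

#' Generate a noisy synthetic force-extension curve
#'
#' Solves the WLC force-extension relation for the extension at each force
#' on the grid (monotone root finding on x in \[0, Lc)) and adds Gaussian
#' extension noise.  Forces outside the (0.01, 50) pN validity window are
#' dropped with a warning.
#'
#' @param P persistence length in nm.
#' @param Lc contour length in nm.
#' @param forces force grid in pN; default 40 log-spaced points over
#'   0.05-30 pN.
#' @param noise_x Gaussian extension noise sigma in nm.
#' @param seed optional integer seed.
#' @param T temperature in K.
#' @param coeffs WLC correction coefficients.
#' @param molecule_id,ion,conc_mM labels carried on the curve.
#' @return a [ForceExtensionCurve-class].
#' @export
synthForceExtension <- function(P, Lc,
                                forces = exp(seq(log(0.05), log(30),
                                                 length.out = 40)),
                                noise_x = 0, seed = NULL, T = 298,
                                coeffs = bouchiatCoefficients(),
                                molecule_id = "synthetic", ion = "Na",
                                conc_mM = 150) {
  if (P <= 0 || Lc <= 0) stop("P and Lc must be > 0")
  ok <- forces > 0.01 & forces < 50
  if (!all(ok)) {
    warning(sum(!ok), " force(s) outside the (0.01, 50) pN validity window",
            " were dropped")
    forces <- forces[ok]
  }
  if (!length(forces)) stop("no forces left inside the validity window")
  x <- vapply(forces, .invertWlc, 0, P = P, Lc = Lc, T = T, coeffs = coeffs)
  if (noise_x > 0)
    x <- withSeed(seed, x + stats::rnorm(length(x), 0, noise_x))
  x <- pmax(x, 0)
  new("ForceExtensionCurve", extension_nm = x, force_pN = forces,
      temperature_K = T, molecule_id = molecule_id, ion = ion,
      conc_mM = conc_mM)
}

#' Configuration for the trajectory generator
#'
#' Collects every knob of the synthetic MD surrogate with validated
#' defaults.  Occupancies are planted cation counts per nucleotide in each
#' binding shell; bulk ions fill the box at \code{bulk_mM}.  Noise terms and
#' bend couplings plant controlled signals for the fluctuation and
#' ion-vs-bend analyses.
#'
#' @param seed integer seed; identical configurations give identical
#'   trajectories.
#' @param n_frames number of frames.
#' @param n_bp base pairs per frame (>= 4; default 20, the duplex length
#'   simulated in the study conditions this package emulates).
#' @param form "A" (dsRNA) or "B" (dsDNA).
#' @param true_P generator persistence length in nm.
#' @param segment_Lc default segment contour length for downstream analyses
#'   in nm.
#' @param coord_noise isotropic Gaussian jitter on all coordinates, nm.
#' @param inclination_noise per-base-pair inclination jitter sigma, degrees.
#' @param incl_bend_coupling relative increase of inclination jitter per
#'   radian of whole-molecule bend (plants the inclination-fluctuation vs
#'   bend correlation).
#' @param groove_noise axial phosphate jitter sigma, nm.
#' @param groove_bend_coupling relative increase of groove jitter per radian
#'   of bend.
#' @param occ_external,occ_internal_major,occ_internal_minor planted cation
#'   occupancies per nucleotide in each shell, in \[0, 1\].
#' @param ext_bend_slope extra external occupancy per radian of
#'   whole-molecule bend (plants the ion-binding vs bend correlation).
#' @param bulk_mM bulk salt concentration in mM.
#' @param ion_species cation species, "Na" or "Li".
#' @param binding_offset additive external-occupancy offset applied when
#'   \code{ion_species = "Li"} (parameterizes the stronger Li+ affinity; not
#'   derived).
#' @param neutral_phosphates logical; TRUE zeroes the phosphate charges
#'   (the electrically neutral construct) and suppresses neutralizing
#'   counterions.
#' @param box_margin solvent margin of the rectangular box around the helix
#'   bounding box, nm.
#' @return a validated configuration list of class "helixbendGenConfig".
#' @export
generatorConfig <- function(seed = 1, n_frames = 2000, n_bp = 20,
                            form = "B", true_P = 47, segment_Lc = 3.3,
                            coord_noise = 0, inclination_noise = 0,
                            incl_bend_coupling = 0, groove_noise = 0,
                            groove_bend_coupling = 0,
                            occ_external = 0, occ_internal_major = 0,
                            occ_internal_minor = 0, ext_bend_slope = 0,
                            bulk_mM = 0, ion_species = "Na",
                            binding_offset = 0, neutral_phosphates = FALSE,
                            box_margin = 3) {
  cfg <- list(seed = seed, n_frames = n_frames, n_bp = n_bp, form = form,
              true_P = true_P, segment_Lc = segment_Lc,
              coord_noise = coord_noise,
              inclination_noise = inclination_noise,
              incl_bend_coupling = incl_bend_coupling,
              groove_noise = groove_noise,
              groove_bend_coupling = groove_bend_coupling,
              occ_external = occ_external,
              occ_internal_major = occ_internal_major,
              occ_internal_minor = occ_internal_minor,
              ext_bend_slope = ext_bend_slope, bulk_mM = bulk_mM,
              ion_species = ion_species, binding_offset = binding_offset,
              neutral_phosphates = neutral_phosphates,
              box_margin = box_margin)
  occ <- c(cfg$occ_external, cfg$occ_internal_major, cfg$occ_internal_minor)
  if (any(occ < 0 | occ > 1)) stop("occupancies must lie in [0, 1]")
  if (cfg$n_frames < 1) stop("n_frames must be >= 1")
  if (cfg$n_bp < 4) stop("n_bp must be >= 4")
  if (cfg$true_P <= 0) stop("true_P must be > 0")
  if (cfg$bulk_mM < 0) stop("bulk_mM must be >= 0")
  if (!cfg$ion_species %in% c("Na", "Li")) stop("ion_species must be Na or Li")
  class(cfg) <- "helixbendGenConfig"
  cfg
}

# core ion placement (assumes the caller controls the RNG); returns a
# data.frame species/charge/x/y/z
.placeIonsCore <- function(frame, config, occ_external = NULL) {
  form <- frame@form
  n_bp <- nBasePairs(frame)
  n_nt <- 2 * n_bp
  R <- form@helical_radius
  occ_ext <- if (is.null(occ_external)) config$occ_external else occ_external
  if (config$ion_species == "Li")
    occ_ext <- min(1, max(0, occ_ext + config$binding_offset))
  cat_sp <- config$ion_species

  allxyz <- rbind(frame@p1, frame@p2, frame@origin)
  lo <- apply(allxyz, 2, min) - config$box_margin
  hi <- apply(allxyz, 2, max) + config$box_margin
  vol <- prod(hi - lo)

  ax <- centralAxis(frame)
  res <- list()

  # external: radially outward from a random phosphate, within 6 A of it
  n_ext <- stats::rpois(1, occ_ext * n_nt)
  if (n_ext > 0) {
    k <- sample.int(n_bp, n_ext, replace = TRUE)
    strand <- sample(c(1, 2), n_ext, replace = TRUE)
    pos <- matrix(0, n_ext, 3)
    for (j in seq_len(n_ext)) {
      pp <- if (strand[j] == 1) frame@p1[k[j], ] else frame@p2[k[j], ]
      rad <- .unit(pp - ax$points[k[j], ])
      pos[j, ] <- pp + rad * stats::runif(1, 0.05, 0.55)
    }
    res$ext <- data.frame(species = cat_sp, charge = 1,
                          x = pos[, 1], y = pos[, 2], z = pos[, 3])
  }

  # internal: inside the groove sector at small axis distance
  az <- .phosphateAzimuths(form)
  fm <- form@groove_fractions[["minor"]]
  placeInternal <- function(n_int, sector) {
    if (n_int == 0) return(NULL)
    # interior base pairs only: the rod has no caps beyond the ends
    k <- sample(2:(n_bp - 1), n_int, replace = TRUE)
    margin <- 0.15
    alpha <- if (sector == "minor")
      stats::runif(n_int, az[["a1"]] + margin, az[["a2"]] - margin)
    else {
      span <- 2 * pi - 2 * pi * fm
      (az[["a2"]] + margin + stats::runif(n_int, 0, span - 2 * margin)) %% (2 * pi)
    }
    r <- stats::runif(n_int, 0.2, 0.8)
    dz <- stats::runif(n_int, -form@rise_per_bp / 2, form@rise_per_bp / 2)
    lin <- .inplaneLong(frame)
    pos <- frame@origin[k, , drop = FALSE] +
      r * (cos(alpha) * frame@shrt[k, , drop = FALSE] +
           sin(alpha) * lin[k, , drop = FALSE]) +
      dz * ax$tangent_bp[k, , drop = FALSE]
    data.frame(species = cat_sp, charge = 1,
               x = pos[, 1], y = pos[, 2], z = pos[, 3])
  }
  res$maj <- placeInternal(stats::rpois(1, config$occ_internal_major * n_nt),
                           "major")
  res$min <- placeInternal(stats::rpois(1, config$occ_internal_minor * n_nt),
                           "minor")

  # bulk: equal numbers of cations and anions uniform in the box
  n_bulk <- stats::rpois(1, config$bulk_mM * vol * .mM_per_nm3)
  if (n_bulk > 0) {
    unif <- function(n) cbind(stats::runif(n, lo[1], hi[1]),
                              stats::runif(n, lo[2], hi[2]),
                              stats::runif(n, lo[3], hi[3]))
    b1 <- unif(n_bulk); b2 <- unif(n_bulk)
    res$bulkc <- data.frame(species = cat_sp, charge = 1,
                            x = b1[, 1], y = b1[, 2], z = b1[, 3])
    res$bulka <- data.frame(species = "Cl", charge = -1,
                            x = b2[, 1], y = b2[, 2], z = b2[, 3])
  }

  ions <- do.call(rbind, res)
  if (is.null(ions))
    ions <- data.frame(species = character(), charge = numeric(),
                       x = numeric(), y = numeric(), z = numeric())

  # neutralize the helix charge with a diffuse counterion background:
  # uniform in the box but rejected from the binding shells, so the
  # planted shell occupancies stay unbiased
  if (!config$neutral_phosphates && frame@phosphate_charge != 0) {
    deficit <- round(-(frame@phosphate_charge * n_nt) - sum(ions$charge))
    if (deficit != 0) {
      nn <- abs(deficit)
      kept <- matrix(0, 0, 3)
      while (nrow(kept) < nn) {
        cand <- cbind(stats::runif(2 * nn, lo[1], hi[1]),
                      stats::runif(2 * nn, lo[2], hi[2]),
                      stats::runif(2 * nn, lo[3], hi[3]))
        cl <- classifyIons(frame, data.frame(x = cand[, 1], y = cand[, 2],
                                             z = cand[, 3]))
        kept <- rbind(kept, cand[cl$shell == "bulk", , drop = FALSE])
      }
      kept <- kept[seq_len(nn), , drop = FALSE]
      res2 <- data.frame(
        species = if (deficit > 0) cat_sp else "Cl",
        charge = if (deficit > 0) 1 else -1,
        x = kept[, 1], y = kept[, 2], z = kept[, 3])
      ions <- rbind(ions, res2)
    }
  }
  if (nrow(ions) > 15 * vol)
    stop("box too small to hold the requested ions")
  rownames(ions) <- NULL
  ions
}

# long-axis direction with the inclination removed (in the plane normal to
# the local bp tangent); used for azimuthal placement and classification
.inplaneLong <- function(frame) {
  tang <- centralAxis(frame)$tangent_bp
  l <- frame@lng - tang * rowSums(frame@lng * tang)
  l / sqrt(rowSums(l^2))
}

#' Place ions around a helix conformation
#'
#' Plants the configured mean cation occupancies per nucleotide in the
#' external (phosphate-shell) and internal (major/minor groove) binding
#' shells, fills the box with bulk ion pairs at the configured
#' concentration, and adds uniformly placed counterions so the box is
#' charge-neutral (unless the phosphates are neutral).  Counts per shell are
#' Poisson with the configured means.
#'
#' @param frame a [HelixFrame-class].
#' @param config a [generatorConfig()] list.
#' @param seed optional seed.
#' @return data.frame with columns species, charge, x, y, z (nm).
#' @export
placeIons <- function(frame, config, seed = NULL) {
  stopifnot(is(frame, "HelixFrame"))
  withSeed(seed, .placeIonsCore(frame, config))
}

#' Generate a synthetic helix trajectory
#'
#' Builds \code{n_frames} independent conformations of an idealized duplex
#' as discrete worm-like chains: every base step receives an independent
#' bend drawn from the WLC step density
#' p(phi) ~ sin(phi) exp(-P phi^2 / 2 h) (h = rise per bp) about a uniform
#' in-plane azimuth, plus the configured twist.  Segment bending angles over
#' any fixed contour length then follow the WLC distribution at
#' \code{true_P}.  Optional planted signals: inclination and groove jitter
#' whose amplitude grows with the frame's bend, and external ion occupancy
#' coupled to the bend.
#'
#' @param config a [generatorConfig()] list.
#' @return a [HelixTrajectory-class]; per-frame generator bend angles are
#'   recorded in \code{frameMeta}.
#' @export
sampleTrajectory <- function(config) {
  if (!inherits(config, "helixbendGenConfig"))
    config <- do.call(generatorConfig, config)
  withSeed(config$seed, .sampleTrajectoryCore(config))
}

.sampleTrajectoryCore <- function(config) {
  form <- helixForm(config$form)
  n <- config$n_bp; m <- config$n_frames
  h <- form@rise_per_bp
  Om <- .deg2rad(form@twist_per_bp)
  eta0 <- .deg2rad(form@inclination0)
  R <- form@helical_radius
  az <- .phosphateAzimuths(form)
  P <- config$true_P
  qP <- if (config$neutral_phosphates) 0 else -1

  dims <- c(n, 3, m)
  p1a <- array(0, dims); p2a <- array(0, dims); oa <- array(0, dims)
  na_ <- array(0, dims); la <- array(0, dims); sa_ <- array(0, dims)

  O <- matrix(0, m, 3)
  tang <- matrix(rep(c(0, 0, 1), each = m), m, 3)
  sax <- matrix(rep(c(1, 0, 0), each = m), m, 3)
  lax <- matrix(rep(c(0, 1, 0), each = m), m, 3)
  t_first <- NULL; t_last <- NULL

  for (k in seq_len(n)) {
    lng <- lax * cos(eta0) + tang * sin(eta0)
    nrm <- tang * cos(eta0) - lax * sin(eta0)
    p1 <- O + R * (cos(az[["a1"]]) * sax + sin(az[["a1"]]) * lax)
    p2 <- O + R * (cos(az[["a2"]]) * sax + sin(az[["a2"]]) * lax)
    oa[k, , ] <- t(O); p1a[k, , ] <- t(p1); p2a[k, , ] <- t(p2)
    na_[k, , ] <- t(nrm); la[k, , ] <- t(lng); sa_[k, , ] <- t(sax)
    if (k < n) {
      phi <- .sampleTheta(m, P, h)
      psi <- stats::runif(m, 0, 2 * pi)
      axs <- cos(psi) * sax + sin(psi) * lax
      tang <- .rotateRows(tang, axs, phi)
      sax <- .rotateRows(sax, axs, phi)
      lax <- .rotateRows(lax, axs, phi)
      sax <- .rotateRows(sax, tang, Om)
      lax <- .rotateRows(lax, tang, Om)
      O <- O + h * tang
      if (k == 1) t_first <- tang
      if (k == n - 1) t_last <- tang
    }
  }
  theta <- acos(pmin(1, pmax(-1, rowSums(t_first * t_last))))

  # planted noise signals
  if (config$inclination_noise > 0) {
    sd_f <- .deg2rad(config$inclination_noise) *
      (1 + config$incl_bend_coupling * theta)
    for (f in seq_len(m)) {
      delta <- stats::rnorm(n, 0, sd_f[f])
      sh <- sa_[, , f]; lg <- la[, , f]; nm_ <- na_[, , f]
      la[, , f] <- .rotateRows(lg, sh, delta)
      na_[, , f] <- .rotateRows(nm_, sh, delta)
    }
  }
  if (config$groove_noise > 0) {
    # cross-strand axial jitter: displacing strand-2 phosphates along the
    # local axis moves the minor and major gaps of nearby positions in the
    # same direction, so it plants a total-groove-width fluctuation signal
    # (strand-1 jitter would move d and D oppositely and cancel in D + d)
    sd_g <- config$groove_noise * (1 + config$groove_bend_coupling * theta)
    for (f in seq_len(m)) {
      nm_ <- na_[, , f]
      p2a[, , f] <- p2a[, , f] + nm_ * stats::rnorm(n, 0, sd_g[f])
    }
  }
  if (config$coord_noise > 0) {
    jit <- function(a) a + array(stats::rnorm(length(a), 0, config$coord_noise),
                                 dim = dim(a))
    p1a <- jit(p1a); p2a <- jit(p2a); oa <- jit(oa)
  }

  meta <- data.frame(frame = seq_len(m), theta_deg = .rad2deg(theta))

  traj <- new("HelixTrajectory", p1 = p1a, p2 = p2a, origin = oa,
              nrm = na_, lng = la, shrt = sa_,
              ions = data.frame(frame = numeric(), species = character(),
                                charge = numeric(), x = numeric(),
                                y = numeric(), z = numeric()),
              frameMeta = meta, form = form, phosphate_charge = qP,
              config = unclass(config))

  wantIons <- config$occ_external > 0 || config$occ_internal_major > 0 ||
    config$occ_internal_minor > 0 || config$bulk_mM > 0
  if (wantIons) {
    ion_list <- vector("list", m)
    for (f in seq_len(m)) {
      fr <- getFrame(traj, f)
      occ <- min(1, max(0, config$occ_external +
                          config$ext_bend_slope * theta[f]))
      df <- .placeIonsCore(fr, config, occ_external = occ)
      if (nrow(df)) df <- cbind(frame = f, df)
      ion_list[[f]] <- df
    }
    ion_list <- ion_list[vapply(ion_list, nrow, 0L) > 0]
    if (length(ion_list)) traj@ions <- do.call(rbind, ion_list)
  }
  traj
}
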