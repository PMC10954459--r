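test_that("inclination matches its projection definition", {
  frB <- idealB(20)
  expect_true(all(abs(inclination(frB) - (-1)) < 1e-6))
  frA <- idealA(20)
  expect_true(all(abs(inclination(frA) - 17) < 1e-6))

  # dual route on an arbitrary frame: asin(long axis . local tangent)
  pf <- perturbedFrame(14)
  tb <- centralAxis(pf)$tangent_bp
  oracle <- asin(pmin(1, pmax(-1, rowSums(pf@lng * tb)))) * 180 / pi
  expect_equal(inclination(pf), oracle, tolerance = 1e-6)

  # bend direction moves the pivot inclination as the groove geometry says
  i0 <- inclination(frB, 10)
  expect_gt(inclination(bendHelix(frB, 20, "major"), 10), i0)
  expect_lt(inclination(bendHelix(frB, 20, "minor"), 10), i0)
})

test_that("axial groove widths sum to the pitch on ideal helices", {
  frB <- idealB(22)
  gw <- axialGrooveWidths(frB)
  pitch <- 360 / frB@form@twist_per_bp * frB@form@rise_per_bp
  expect_true(all(abs(gw$total - pitch) < 1e-3))
  expect_lt(sd(gw$total), 1e-9)
  expect_equal(mean(gw$d), pitch * 0.35, tolerance = 1e-6)

  # squeezing the minor groove (azimuthal phosphate shift): d down,
  # D up, total unchanged
  squeezed <- helixForm("B")
  squeezed@groove_fractions <- c(major = 0.70, minor = 0.30)
  gw2 <- axialGrooveWidths(makeIdealHelix(squeezed, 22))
  expect_lt(mean(gw2$d), mean(gw$d))
  expect_gt(mean(gw2$D), mean(gw$D))
  expect_equal(mean(gw2$total), mean(gw$total), tolerance = 1e-6)
})

test_that("groove widths match a brute-force crossing search", {
  pf <- perturbedFrame(23, n_bp = 22)
  gw <- axialGrooveWidths(pf)
  hc <- helixbend:::.phosphateHelixCoords(pf)
  # oracle: scan consecutive strand-2 phosphates for azimuth brackets of
  # each strand-1 phosphate (mod 2 pi) and interpolate the crossing
  for (row in seq_len(nrow(gw))) {
    i <- gw$bp[row]
    crossings <- c()
    for (j in seq_len(length(hc$phi2) - 1)) {
      for (k in -3:3) {
        tgt <- hc$phi1[i] + 2 * pi * k
        lo <- hc$phi2[j]; hi <- hc$phi2[j + 1]
        if ((lo - tgt) * (hi - tgt) <= 0 && lo != hi) {
          w <- (tgt - lo) / (hi - lo)
          crossings <- c(crossings, (1 - w) * hc$s2[j] + w * hc$s2[j + 1])
        }
      }
    }
    below <- crossings[crossings < hc$s1[i]]
    above <- crossings[crossings >= hc$s1[i]]
    expect_equal(gw$d[row], hc$s1[i] - max(below), tolerance = 1e-9)
    expect_equal(gw$D[row], min(above) - hc$s1[i], tolerance = 1e-9)
  }
})

test_that("geometry is invariant to rigid-body transforms", {
  pf <- bendHelix(idealB(22), 18, "major")
  tf <- transformFrame(pf, randomRotation(7), c(-3, 8, 1))
  expect_equal(inclination(pf), inclination(tf), tolerance = 1e-9)
  g1 <- axialGrooveWidths(pf); g2 <- axialGrooveWidths(tf)
  expect_equal(g1$total, g2$total, tolerance = 1e-9)
  h1 <- helicalParameters(pf)$step; h2 <- helicalParameters(tf)$step
  expect_equal(h1$twist, h2$twist, tolerance = 1e-9)
  expect_equal(h1$rise, h2$rise, tolerance = 1e-9)
})

test_that("fluctuation profiles separate rigid and noisy conformations", {
  fr <- idealB(20)
  rigid <- helixbend:::.trajFromFrames(rep(list(fr), 4), NULL, fr@form, -1)
  fi <- fluctuationProfile(rigid, "inclination")
  expect_lt(fi$mean, 1e-9)
  fg <- fluctuationProfile(rigid, "total_groove_width")
  expect_lt(fg$mean, 1e-9)

  # planted inclination jitter: per-frame SD matches a direct oracle
  tr <- sampleTrajectory(generatorConfig(seed = 15, n_frames = 25,
                                         n_bp = 20, true_P = 47,
                                         inclination_noise = 3))
  fi2 <- fluctuationProfile(tr, "inclination")
  oracle <- vapply(seq_len(25), function(f) {
    frm <- getFrame(tr, f)
    tb <- centralAxis(frm)$tangent_bp
    sd(asin(pmin(1, pmax(-1, rowSums(frm@lng * tb)))) * 180 / pi)
  }, 0)
  expect_equal(fi2$per_frame$sd, oracle, tolerance = 1e-9)

  # frames with larger bend carry larger inclination spread under coupling
  trc <- sampleTrajectory(generatorConfig(seed = 16, n_frames = 600,
                                          n_bp = 20, true_P = 47,
                                          inclination_noise = 3,
                                          incl_bend_coupling = 2))
  th <- trc@frameMeta$theta_deg
  sdv <- fluctuationProfile(trc, "inclination")$per_frame$sd
  hi <- th > median(th)
  expect_gt(mean(sdv[hi]), mean(sdv[!hi]))
})

test_that("correlations with bend recover planted signals", {
  # calibrated configuration: inclination fluctuation vs bend at PCC ~ 0.4
  tr <- sampleTrajectory(generatorConfig(seed = 21, n_frames = 4000,
                                         n_bp = 20, form = "B",
                                         true_P = 47,
                                         inclination_noise = 3,
                                         incl_bend_coupling = 1))
  pc <- correlateWithBend(tr, observables = "inclination")
  expect_equal(pc$r[pc$observable == "sd_inclination"], 0.40,
               tolerance = 0.05 / 0.40)

  # dual route: recompute the same Pearson r by hand from the trajectory
  n <- nBasePairs(tr)
  th <- vapply(seq_len(500), function(f)
    bendingAngle(getFrame(tr, f), 4, n - 6), 0)
  sdv <- vapply(seq_len(500), function(f)
    sd(inclination(getFrame(tr, f))), 0)
  sub <- tr
  idx <- seq_len(500)
  for (nm in c("p1", "p2", "origin", "nrm", "lng", "shrt"))
    slot(sub, nm) <- slot(tr, nm)[, , idx, drop = FALSE]
  sub@frameMeta <- tr@frameMeta[idx, ]
  pc500 <- correlateWithBend(sub, observables = "inclination")
  expect_equal(pc500$r, cor(th, sdv), tolerance = 1e-9)

  # groove hierarchy under a planted total-width coupling
  trg <- sampleTrajectory(generatorConfig(seed = 41, n_frames = 2500,
                                          n_bp = 24, form = "B",
                                          true_P = 47,
                                          groove_noise = 0.04,
                                          groove_bend_coupling = 2))
  pg <- correlateWithBend(trg, observables = "grooves")
  r <- setNames(pg$r, pg$observable)
  expect_gt(r[["sd_total"]], r[["sd_D"]])
  expect_gt(r[["sd_D"]], r[["sd_d"]])

  # the step-parameter screen reports all twelve observables
  small <- sampleTrajectory(generatorConfig(seed = 2, n_frames = 40,
                                            n_bp = 16, true_P = 47))
  scr <- correlateWithBend(small, observables = "step_params")
  expect_identical(nrow(scr), 12L)
  expect_true(all(abs(scr$r[is.finite(scr$r)]) <= 1))
})
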