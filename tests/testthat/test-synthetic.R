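test_that("ideal helices have the constructed geometry", {
  frB <- idealB(11)
  expect_equal(frB@origin[11, 3] - frB@origin[1, 3], 10 * 0.34)

  frA <- idealA(20)
  expect_lt(bendingAngle(frA), 1e-9)

  # every phosphorus lies at the helical radius from the straight axis
  fr <- idealB(20)
  for (P in list(fr@p1, fr@p2)) {
    d_axis <- sqrt(P[, 1]^2 + P[, 2]^2)   # axis is the z line
    expect_true(all(abs(d_axis - fr@form@helical_radius) < 1e-9))
  }
  expect_true(all(abs(inclination(frA)[3:18] - 17) < 1e-6))

  expect_error(makeIdealHelix("B", 3), "at least 4")
})

test_that("bendHelix produces the requested bend with conserved bonds", {
  fr <- idealB(20)
  expect_identical(bendHelix(fr, 0), fr)
  expect_error(bendHelix(fr, 120), "90")

  b <- bendHelix(fr, 20, "major")
  expect_equal(bendingAngle(b), 20, tolerance = 0.1 / 20)

  # inclination coupling: major bend raises, minor bend lowers
  i0 <- inclination(fr, 10)
  expect_gt(inclination(bendHelix(fr, 20, "major"), 10), i0)
  expect_lt(inclination(bendHelix(fr, 20, "minor"), 10), i0)

  # bond geometry: inter-phosphate distances change < 1% for theta <= 30
  for (form in c("A", "B")) {
    fr2 <- makeIdealHelix(form, 24)
    for (th in c(10, 20, 30)) {
      bb <- bendHelix(fr2, th, "major")
      for (sl in c("p1", "p2")) {
        l0 <- sqrt(rowSums(diff(slot(fr2, sl))^2))
        l1 <- sqrt(rowSums(diff(slot(bb, sl))^2))
        expect_lt(max(abs(l1 - l0) / l0), 0.01)
      }
    }
  }
})

test_that("WLC angle sampler matches its target distribution", {
  expect_error(sampleWlcAngles(-1, 3.3, 10), "> 0")

  # seeded determinism
  e1 <- sampleWlcAngles(39, 3.3, 1000, seed = 5)
  e2 <- sampleWlcAngles(39, 3.3, 1000, seed = 5)
  expect_identical(angles(e1), angles(e2))

  # stiff limit: angles collapse toward zero
  expect_lt(mean(angles(sampleWlcAngles(1e4, 3.3, 2000, seed = 1))), 3)

  # Kolmogorov distance against an independent quadrature CDF
  P <- 39; Lc <- 3.3
  th <- sort(angles(sampleWlcAngles(P, Lc, 1e5, seed = 11)) * pi / 180)
  grid <- seq(0, pi, length.out = 2e5)
  f <- sin(grid) * exp(-P * grid^2 / (2 * Lc))
  cdf <- cumsum(c(0, (f[-1] + f[-length(f)]) / 2 * diff(grid)))
  cdf <- cdf / cdf[length(cdf)]
  Ftarget <- approx(grid, cdf, xout = th)$y
  Femp <- seq_along(th) / length(th)
  expect_lt(max(abs(Femp - Ftarget)), 0.005)

  # round trip through the distribution fit
  ens <- sampleWlcAngles(39, 3.3, 2e5, seed = 7)
  fit <- fitPFromPdf(angleHistogram(ens), 3.3)
  expect_equal(fit$P, 39, tolerance = 0.02)
})

test_that("WLC sampler is unbiased over replicates", {
  fits <- vapply(1:20, function(s) {
    ens <- sampleWlcAngles(47, 3.3, 2e4, seed = 100 + s)
    fitPFromPdf(angleHistogram(ens), 3.3, min_count = 10)$P
  }, 0)
  expect_lt(abs(mean(fits) - 47) / 47, 0.02)
})

test_that("trajectory generator round-trips the persistence length", {
  cfg <- generatorConfig(seed = 3, n_frames = 12000, n_bp = 20, form = "A",
                         true_P = 55)
  tr <- sampleTrajectory(cfg)
  expect_identical(nFrames(tr), 12000L)
  ens <- collectSegments(tr)
  fit <- fitPFromPdf(angleHistogram(ens), ens@segment_Lc)
  expect_equal(fit$P, 55, tolerance = 0.05)

  # byte-identical repeat under the same config
  c2 <- generatorConfig(seed = 77, n_frames = 50, n_bp = 12, form = "B",
                        true_P = 47, occ_external = 0.2, bulk_mM = 100)
  ta <- sampleTrajectory(c2); tb <- sampleTrajectory(c2)
  expect_identical(ta@origin, tb@origin)
  expect_identical(ta@ions, tb@ions)

  # single-frame trajectory: downstream fitting refuses
  t1 <- sampleTrajectory(generatorConfig(seed = 1, n_frames = 1, n_bp = 20))
  e1 <- collectSegments(t1, 11)
  expect_error(fitPFromPdf(angleHistogram(e1), e1@segment_Lc), "too few")
})

test_that("ion placement plants the configured occupancies", {
  fr <- idealB(20)

  # empty configuration with neutral phosphates: no ions at all
  frn <- idealB(20, charge = 0)
  cfg0 <- generatorConfig(seed = 1, neutral_phosphates = TRUE)
  expect_identical(nrow(placeIons(frn, cfg0, seed = 1)), 0L)

  # charge neutrality: cation - anion - helix charge = 0
  cfg <- generatorConfig(seed = 1, occ_external = 0.36,
                         occ_internal_major = 0.1,
                         occ_internal_minor = 0.05, bulk_mM = 150)
  for (s in 1:5) {
    io <- placeIons(fr, cfg, seed = s)
    expect_identical(sum(io$charge), 40)   # cancels the 40 phosphates
  }

  # external occupancy recovered within 3 standard errors
  set.seed(42)
  ext <- replicate(250, {
    io <- placeIons(fr, cfg, seed = sample.int(1e6, 1))
    cl <- classifyIons(fr, io)
    sum(cl$charge[cl$shell == "external"]) / 40
  })
  se <- sd(ext) / sqrt(length(ext))
  expect_lt(abs(mean(ext) - 0.36), 3 * se + 0.01)

  # a box that cannot hold the requested ions errors
  cfg_big <- generatorConfig(seed = 1, bulk_mM = 2e5)
  expect_error(placeIons(fr, cfg_big, seed = 1), "box too small")

  expect_error(generatorConfig(occ_external = 1.2), "\\[0, 1\\]")
})

test_that("synthetic force-extension traces invert the WLC exactly", {
  # noiseless round trip recovers the generator parameters
  cu <- synthForceExtension(50, 4675, noise_x = 0)
  ft <- fitForceExtension(cu)
  expect_equal(ft@P, 50, tolerance = 1e-6)
  expect_equal(ft@Lc, 4675, tolerance = 1e-6)

  # zero-force limit: extension follows the linear entropic-spring law
  # x/Lc -> (2/3) F P / kBT as F -> 0
  lo <- synthForceExtension(50, 100, forces = c(0.011, 0.02, 0.05), noise_x = 0)
  expect_equal(lo@extension_nm[1], 100 * 2 / 3 * 0.011 * 50 / kBT(298),
               tolerance = 0.15)
  expect_true(all(diff(lo@extension_nm) > 0))

  # mid-range inversion agrees with an independent bisection oracle
  P <- 47; Lc <- 1000
  Fmid <- evalWlcForce(P, Lc, Lc / 2)
  x <- synthForceExtension(P, Lc, forces = Fmid, noise_x = 0)@extension_nm
  lohi <- c(0, Lc * (1 - 1e-9))
  for (i in 1:60) {                       # plain bisection
    mid <- mean(lohi)
    if (evalWlcForce(P, Lc, mid) < Fmid) lohi[1] <- mid else lohi[2] <- mid
  }
  expect_equal(x, mean(lohi), tolerance = 1e-10)
  expect_equal(x, Lc / 2, tolerance = 1e-9)

  # forces outside the validity window are flagged and dropped
  expect_warning(synthForceExtension(50, 100, forces = c(0.005, 1, 60)),
                 "validity window")
})
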