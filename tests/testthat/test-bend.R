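test_that("the central axis tracks the conformation", {
  fr <- idealB(20)
  ax <- centralAxis(fr)
  # straight helix: axis points collinear
  dev <- sqrt(ax$points[, 1]^2 + ax$points[, 2]^2)
  expect_lt(max(dev), 1e-9)

  # a literal single kink concentrates the tangent change at the pivot
  kinked <- bendHelix(fr, 25, "major", pivot_step = 10, window = 1)
  tg <- centralAxis(kinked)$tangents
  turns <- acos(pmin(1, rowSums(tg[-1, ] * tg[-nrow(tg), ]))) * 180 / pi
  expect_gt(max(turns), 5)
  expect_lt(max(turns[-(8:11)]), 1e-6)    # flat away from the pivot

  # smoothed step tangents equal centred differences of the raw centers
  pf <- perturbedFrame(8)
  tg2 <- centralAxis(pf)$tangents
  raw <- rawCenteredTangents(pf)
  ang <- acos(pmin(1, rowSums(tg2[2:(nrow(tg2) - 1), ] * raw))) * 180 / pi
  expect_lt(max(ang), 0.5)

  bad <- fr
  bad@origin <- matrix(1, 20, 3)
  expect_error(centralAxis(bad), "degenerate")
})

test_that("segment bending angles come from the end-step tangents", {
  fr <- idealB(20)
  expect_lt(bendingAngle(fr, 4, 13), 1e-9)

  kinked <- bendHelix(fr, 25, "major", pivot_step = 10, window = 1)
  expect_equal(bendingAngle(kinked, 4, 14), 25, tolerance = 0.5 / 25)

  # dual route: independent dot-product of the end tangents
  pf <- perturbedFrame(5)
  tg <- centralAxis(pf)$tangents
  th_oracle <- acos(sum(tg[4, ] * tg[4 + 13 - 2, ])) * 180 / pi
  expect_equal(bendingAngle(pf, 4, 13), th_oracle, tolerance = 1e-9)

  expect_error(bendingAngle(fr, 15, 13), "out of bounds")
})

test_that("segment windows enumerate correctly", {
  tr <- sampleTrajectory(generatorConfig(seed = 2, n_frames = 3, n_bp = 20))
  # enumeration oracle: starts s with s >= excl+1, s+nseg-1 <= n-excl
  oracleCount <- function(n, nseg, excl)
    max(0, (n - excl) - (nseg - 1) - (excl + 1) + 1)
  expect_identical(collectSegments(tr, 13, 3)@meta$n_windows,
                   as.integer(oracleCount(20, 13, 3)))
  expect_identical(collectSegments(tr, 13, 3)@meta$n_windows, 2L)
  expect_identical(collectSegments(tr, 11, 3)@meta$n_windows, 4L)
  expect_identical(collectSegments(tr, 20, 0)@meta$n_windows, 1L)
  expect_error(collectSegments(tr, 15, 3), "no eligible")
})

test_that("angle histograms normalize and feed the persistence fits", {
  ens <- sampleWlcAngles(47, 3.3, 5000, seed = 2)
  h <- angleHistogram(ens)
  expect_equal(sum(h@density * diff(h@breaks_deg)), 1, tolerance = 1e-12)

  # analytic density tabulated on the grid recovers P to < 0.5%
  P <- 39; Lc <- 3.3
  h0 <- angleHistogram(numeric(0))
  mids <- h0@mids_deg
  th <- mids * pi / 180
  dens <- sin(th) * exp(-P * th^2 / (2 * Lc))
  counts <- round(dens / sum(dens) * 2e7)
  hh <- new("AngleHistogram", breaks_deg = h0@breaks_deg, mids_deg = mids,
            counts = counts,
            density = counts / (sum(counts) * diff(h0@breaks_deg)),
            n = sum(counts))
  expect_equal(fitPFromPdf(hh, Lc)$P, 39, tolerance = 0.005)

  # floppy limit: uniform tangents on the sphere give P = 0
  set.seed(6)
  u <- acos(runif(2e5, -1, 1)) * 180 / pi
  f0 <- fitPFromPdf(angleHistogram(u), 3.3)
  expect_lt(abs(f0$P), 4 * f0$se + 0.01)

  # benchmark-scale recovery
  e55 <- sampleWlcAngles(refVal("md_rna_nacl_150mM"), 3.3, 2e5, seed = 3)
  expect_equal(fitPFromPdf(angleHistogram(e55), 3.3)$P, 55,
               tolerance = 0.05)
})

test_that("the energy route and the pdf route agree", {
  ens <- sampleWlcAngles(47, 3.3, 5e4, seed = 4)
  h <- angleHistogram(ens)
  prof <- bendingEnergy(h)

  # doubling the counts leaves the profile unchanged
  h2 <- new("AngleHistogram", breaks_deg = h@breaks_deg,
            mids_deg = h@mids_deg, counts = 2 * h@counts,
            density = h@density, n = 2 * h@n)
  expect_equal(bendingEnergy(h2)$E_kBT, prof$E_kBT)

  # exact WLC histogram: profile is P theta^2/(2 Lc) + const
  f_pdf <- fitPFromPdf(h, 3.3)
  f_en <- fitPFromEnergy(prof, 3.3)
  expect_equal(f_en$P, f_pdf$P, tolerance = 1e-9)

  # masked bins stay NA
  expect_true(all(is.na(prof$E_kBT[prof$count == 0])))
})

test_that("angle extraction is invariant to rigid-body transforms", {
  tr <- sampleTrajectory(generatorConfig(seed = 12, n_frames = 40,
                                         n_bp = 20, form = "B",
                                         true_P = 47))
  tr2 <- transformTrajectory(tr, randomRotation(3), c(7, -4, 2))
  e1 <- collectSegments(tr, 11)
  e2 <- collectSegments(tr2, 11)
  expect_equal(angles(e1), angles(e2), tolerance = 1e-9)
})

test_that("the persistence estimator is consistent as n grows", {
  bias <- vapply(c(1e3, 1e4, 1e5), function(n) {
    fits <- vapply(1:8, function(s) {
      ens <- sampleWlcAngles(47, 3.3, n, seed = 1000 * log10(n) + s)
      fitPFromPdf(angleHistogram(ens), 3.3, min_count = 5)$P
    }, 0)
    abs(mean(fits) - 47)
  }, 0)
  expect_true(all(diff(bias) < 0))
})
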