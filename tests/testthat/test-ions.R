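test_that("ions classify into the documented shells", {
  fr <- idealB(20)
  ax <- centralAxis(fr)

  # radially 3 A outside a phosphate: axis distance 13 A -> external
  dir_out <- (fr@p1[10, ] - ax$points[10, ])
  dir_out <- dir_out / sqrt(sum(dir_out^2))
  ion_ext <- fr@p1[10, ] + 0.3 * dir_out
  # axis distance 5 A in the major-groove sector -> internal_major
  # (the short axis points at the major-groove bisector)
  ion_maj <- fr@origin[10, ] + 0.5 * fr@shrt[10, ]
  # 30 A from everything -> bulk
  ion_far <- fr@origin[10, ] + c(3, 0, 0)

  ions <- data.frame(x = c(ion_ext[1], ion_maj[1], ion_far[1]),
                     y = c(ion_ext[2], ion_maj[2], ion_far[2]),
                     z = c(ion_ext[3], ion_maj[3], ion_far[3]),
                     charge = 1, species = "Na")
  cl <- classifyIons(fr, ions)
  expect_identical(cl$shell, c("external", "internal_major", "bulk"))
})

test_that("groove labels take precedence over the phosphate shell", {
  fr <- idealB(20)
  # just inside the helical radius, near the strand-1 phosphate azimuth
  # (within 6 A of the phosphate AND inside the minor-groove sector)
  lin <- helixbend:::.inplaneLong(fr)
  az <- helixbend:::.phosphateAzimuths(fr@form)
  a_in <- az[["a1"]] + 0.25          # a bit into the minor arc
  pos <- fr@origin[10, ] + 0.8 * (cos(a_in) * fr@shrt[10, ] +
                                  sin(a_in) * lin[10, ])
  cl <- classifyIons(fr, data.frame(x = pos[1], y = pos[2], z = pos[3]))
  expect_lte(cl$d_phos, 0.6)
  expect_identical(cl$shell, "internal_minor")
})

test_that("the shell partition is complete and charge-conserving", {
  fr <- idealB(20)
  set.seed(8)
  n <- 10000L
  ions <- data.frame(x = runif(n, -4, 4), y = runif(n, -4, 4),
                     z = runif(n, -3, 10),
                     charge = sample(c(-1, 1), n, TRUE), species = "Na")
  cl <- classifyIons(fr, ions)
  expect_identical(nrow(cl), n)
  expect_true(all(cl$shell %in% c("external", "internal_major",
                                  "internal_minor", "bulk")))
  # signed charge bookkeeping: shells partition the total exactly
  tot <- sum(ions$charge)
  by_shell <- tapply(cl$charge, cl$shell, sum)
  expect_identical(sum(by_shell), tot)
})

test_that("charge fractions report planted occupancies and arithmetic", {
  # constructed frame: 12 cations and 4 anions in the external shell of a
  # 20-bp duplex -> external fraction (12 - 4)/40 = 0.2
  fr <- idealB(20)
  ax <- centralAxis(fr)
  mk <- function(k, q) {
    d <- fr@p1[k, ] - ax$points[k, ]
    p <- fr@p1[k, ] + 0.3 * d / sqrt(sum(d^2))
    data.frame(frame = 1, species = ifelse(q > 0, "Na", "Cl"), charge = q,
               x = p[1], y = p[2], z = p[3])
  }
  ions <- do.call(rbind, c(lapply(3:14, mk, q = 1),
                           lapply(15:18, mk, q = -1)))
  tr <- helixbend:::.trajFromFrames(list(fr), ions, fr@form, -1)
  cf <- chargeFractions(tr)
  expect_equal(cf$summary$mean[cf$summary$shell == "external"], 0.2)
  expect_equal(cf$summary$mean[cf$summary$shell == "total"], 0.2)

  # neutral generator with no ions: all fractions zero
  trn <- sampleTrajectory(generatorConfig(seed = 4, n_frames = 12,
                                          n_bp = 12, bulk_mM = 50,
                                          neutral_phosphates = TRUE))
  trn@ions <- trn@ions[0, ]
  cfn <- chargeFractions(trn)
  expect_true(all(cfn$summary$mean == 0))

  # planted external occupancy at the dsDNA/150 mM benchmark recovered
  occ <- refVal("chargefrac_ext_dna_nacl_150mM")
  trb <- sampleTrajectory(generatorConfig(seed = 21, n_frames = 250,
                                          n_bp = 20, form = "B",
                                          true_P = 47,
                                          occ_external = occ,
                                          bulk_mM = 150))
  cfb <- chargeFractions(trb)
  ext <- cfb$per_frame$external
  se <- sd(ext) / sqrt(length(ext))
  expect_lt(abs(mean(ext) - occ), 3 * se + 0.01)
})

test_that("radial concentration profiles plateau at the bulk value", {
  tr <- sampleTrajectory(generatorConfig(seed = 9, n_frames = 250,
                                         n_bp = 20, form = "B",
                                         true_P = 47, bulk_mM = 150,
                                         neutral_phosphates = TRUE))
  pr <- radialConcentrationProfile(tr, "Na", dr = 0.5)
  plateau <- pr$conc_mM[pr$r_mid > 2.5]
  expect_true(all(abs(plateau - 150) < 10))

  # zero ions give an all-zero profile
  tr0 <- tr; tr0@ions <- tr0@ions[0, ]
  expect_true(all(radialConcentrationProfile(tr0, "Na")$conc_mM == 0))

  # per-shell counts match a brute-force per-ion loop on a few frames
  small <- sampleTrajectory(generatorConfig(seed = 10, n_frames = 12,
                                            n_bp = 12, bulk_mM = 150,
                                            neutral_phosphates = TRUE))
  pr2 <- radialConcentrationProfile(small, "Na", dr = 0.5)
  edges <- seq(0, max(pr2$r_mid) + 0.25, by = 0.5)
  brute <- numeric(length(edges) - 1)
  for (f in seq_len(nFrames(small))) {
    frm <- getFrame(small, f)
    ax <- centralAxis(frm)
    io <- frameIons(small, f)
    io <- io[io$species == "Na", ]
    for (j in seq_len(nrow(io))) {
      p <- c(io$x[j], io$y[j], io$z[j])
      d2 <- colSums((t(ax$points) - p)^2)
      k <- which.min(d2)
      if (k == 1 || k == nrow(ax$points)) next
      v <- p - ax$points[k, ]
      axial <- sum(v * ax$tangent_bp[k, ])
      r <- sqrt(max(0, sum(v^2) - axial^2))
      b <- findInterval(r, edges, rightmost.closed = TRUE)
      if (b >= 1 && b <= length(brute)) brute[b] <- brute[b] + 1
    }
  }
  expect_identical(pr2$count, brute)

  few <- sampleTrajectory(generatorConfig(seed = 2, n_frames = 5,
                                          n_bp = 12, bulk_mM = 50,
                                          neutral_phosphates = TRUE))
  expect_error(radialConcentrationProfile(few, "Na"), "at least 10")
  expect_warning(radialConcentrationProfile(small, "Na", r_max = 20),
                 "truncated")
})

test_that("bend-vs-binding resolves planted and null couplings", {
  # planted: external occupancy increases with the frame bend
  trp <- sampleTrajectory(generatorConfig(seed = 31, n_frames = 1200,
                                          n_bp = 20, form = "B",
                                          true_P = 47, occ_external = 0.3,
                                          ext_bend_slope = 0.5,
                                          neutral_phosphates = TRUE))
  bb <- bendVsBinding(trp)
  expect_gt(bb$pearson[["external"]], 0.25)

  # binned means match a brute-force group-by of the per-frame table
  bins <- floor(bb$per_frame$theta_deg / 5)
  oracle <- tapply(bb$per_frame$external, bins, mean)
  expect_equal(unname(bb$table$mean_external), unname(as.numeric(oracle)))

  # null: occupancy independent of bend
  tr0 <- sampleTrajectory(generatorConfig(seed = 32, n_frames = 5000,
                                          n_bp = 20, form = "B",
                                          true_P = 47, occ_external = 0.3,
                                          neutral_phosphates = TRUE))
  bb0 <- bendVsBinding(tr0)
  expect_lt(abs(bb0$pearson[["external"]]), 0.05)
})
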