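test_that("Debye length follows the square-root screening law", {
  expect_equal(debyeLength(600), debyeLength(150) / 2, tolerance = 1e-12)
  expect_error(debyeLength(0), "> 0")

  # independent constants-based evaluation at 150 mM, 298 K
  lB <- 230.6994 / (78 * 1.380649e-2 * 298)
  kinv <- 1 / sqrt(8 * pi * lB * 150 * 6.02214076e-4)
  expect_equal(debyeLength(150), kinv, tolerance = 1e-10)
})

test_that("screened-Coulomb energies match the pairwise definition", {
  # two unit charges one Bjerrum length apart, unscreened: exactly 1 kBT
  m <- electrostaticModel(150)
  m@kappa_inv <- 1e12
  pts <- rbind(c(0, 0, 0), c(0, 0, bjerrumLength()))
  expect_equal(helixbend:::.screenedCoulomb(pts, c(-1, -1), m), 1,
               tolerance = 1e-9)

  # full screening kills the energy
  m0 <- electrostaticModel(150); m0@kappa_inv <- 1e-4
  fr <- idealB(12)
  expect_lt(abs(electrostaticEnergy(fr, m0)), 1e-12)

  # 50-charge random configuration against an O(N^2) double loop
  set.seed(13)
  pts <- matrix(runif(150, 0, 5), 50, 3)
  q <- sample(c(-1, 1), 50, TRUE)
  mod <- electrostaticModel(150)
  kap <- 1 / mod@kappa_inv
  acc <- 0
  for (i in 1:49) for (j in (i + 1):50) {
    r <- sqrt(sum((pts[i, ] - pts[j, ])^2))
    acc <- acc + q[i] * q[j] * exp(-kap * r) / r
  }
  expect_equal(helixbend:::.screenedCoulomb(pts, q, mod),
               mod@l_B * acc, tolerance = 1e-12)

  # energy decreases monotonically with kappa for like charges
  frq <- idealB(10)
  kinvs <- c(2, 1, 0.5, 0.25)
  E <- vapply(kinvs, function(ki) {
    mm <- electrostaticModel(150); mm@kappa_inv <- ki
    electrostaticEnergy(frq, mm)
  }, 0)
  expect_true(all(diff(E) < 0))

  dup <- frq; dup@p2[3, ] <- dup@p1[3, ]
  expect_error(electrostaticEnergy(dup, mod), "coincident")
})

test_that("electrostatic bending energy is positive and increasing", {
  base <- idealB(20)
  mod <- electrostaticModel(150)
  expect_equal(deltaEel(list(base), base, mod, theta_deg = 0)$dE_el, 0)

  thetas <- seq(5, 40, by = 5)
  prof <- deltaEel(lapply(thetas, function(th) bendHelix(base, th)),
                   base, mod, theta_deg = thetas)
  expect_true(all(prof$dE_el > 0))
  expect_true(all(diff(prof$dE_el) > 0))

  # neutral duplex: dE_el vanishes identically
  b0 <- makeIdealHelix("B", 20, phosphate_charge = 0)
  prof0 <- deltaEel(lapply(c(10, 20), function(th) bendHelix(b0, th)),
                    b0, mod, theta_deg = c(10, 20))
  expect_true(all(prof0$dE_el == 0))
})

test_that("the energy decomposition obeys its exact identities", {
  th <- seq(1, 40, by = 1); Lc <- 3.3
  x <- (th * pi / 180)^2 / (2 * Lc)
  bp <- data.frame(theta_deg = th, E_kBT = 55 * x)
  ep <- data.frame(theta_deg = th, dE_el = 17 * x)
  dec <- decomposeBendingEnergy(bp, ep, Lc)
  expect_equal(dec@P, 55, tolerance = 1e-9)
  expect_equal(dec@P_el, 17, tolerance = 1e-9)
  expect_equal(dec@P_nel, 38, tolerance = 1e-9)
  expect_equal(dec@dE_nel, dec@dE_bend - dec@dE_el)

  # zero electrostatics: P_nel = P
  dec0 <- decomposeBendingEnergy(bp, data.frame(theta_deg = th, dE_el = 0),
                                 Lc)
  expect_equal(dec0@P_el, 0)
  expect_equal(dec0@P_nel, dec0@P)

  # additivity survives noise exactly (linearity of the regression)
  set.seed(5)
  bp_n <- data.frame(theta_deg = th, E_kBT = 55 * x + rnorm(40, 0, 0.02))
  ep_n <- data.frame(theta_deg = th, dE_el = 17 * x + rnorm(40, 0, 0.02))
  dn <- decomposeBendingEnergy(bp_n, ep_n, Lc)
  expect_equal(dn@P, dn@P_el + dn@P_nel, tolerance = 1e-9)

  expect_error(decomposeBendingEnergy(
    bp, data.frame(theta_deg = th + 100, dE_el = 0), Lc),
    "no theta grid")
})

test_that("neutralizing phosphates removes the electrostatic stiffness", {
  # the screened-Coulomb route on a neutral duplex leaves only the
  # intrinsic persistence length
  th <- seq(2, 30, by = 2); Lc <- 3.3
  x <- (th * pi / 180)^2 / (2 * Lc)
  b0 <- makeIdealHelix("B", 16, phosphate_charge = 0)
  mod <- electrostaticModel(150)
  eel <- deltaEel(lapply(th, function(t_) bendHelix(b0, t_)), b0, mod,
                  theta_deg = th)
  dec <- decomposeBendingEnergy(
    data.frame(theta_deg = th, E_kBT = 39 * x), eel, Lc)
  expect_equal(dec@P_el, 0)
  expect_equal(dec@P_nel, dec@P, tolerance = 1e-9)
})
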