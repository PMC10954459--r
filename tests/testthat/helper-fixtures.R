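# shared fixtures and small oracle utilities

idealB <- function(n = 20, charge = -1) makeIdealHelix("B", n, charge)
idealA <- function(n = 20, charge = -1) makeIdealHelix("A", n, charge)

# a thermally perturbed helix conformation (one frame of a seeded chain)
perturbedFrame <- function(seed = 1, n_bp = 20, form = "B", P = 47) {
  tr <- sampleTrajectory(generatorConfig(seed = seed, n_frames = 1,
                                         n_bp = n_bp, form = form,
                                         true_P = P))
  getFrame(tr, 1)
}

# centred finite-difference tangents on the raw base-pair centers
# (independent of centralAxis); interior steps only
rawCenteredTangents <- function(frame) {
  o <- frame@origin
  n <- nrow(o)
  t(vapply(2:(n - 2), function(s) {
    v <- o[s + 2, ] - o[s - 1, ]
    v / sqrt(sum(v^2))
  }, numeric(3)))
}

# random rotation matrix from a seed
randomRotation <- function(seed) {
  set.seed(seed)
  a <- rnorm(3); a <- a / sqrt(sum(a^2))
  ang <- runif(1, 0, pi)
  K <- matrix(c(0, a[3], -a[2], -a[3], 0, a[1], a[2], -a[1], 0), 3, 3)
  diag(3) * cos(ang) + sin(ang) * K + (1 - cos(ang)) * outer(a, a)
}

# apply a rigid-body transform to every frame of a trajectory
transformTrajectory <- function(traj, R, tvec) {
  for (nm in c("p1", "p2", "origin")) {
    a <- slot(traj, nm)
    for (f in seq_len(dim(a)[3]))
      a[, , f] <- sweep(a[, , f] %*% t(R), 2, tvec, "+")
    slot(traj, nm) <- a
  }
  for (nm in c("nrm", "lng", "shrt")) {
    a <- slot(traj, nm)
    for (f in seq_len(dim(a)[3])) a[, , f] <- a[, , f] %*% t(R)
    slot(traj, nm) <- a
  }
  traj
}

refVal <- function(key) referenceValues(key)
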