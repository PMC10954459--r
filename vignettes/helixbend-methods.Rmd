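---
title: "Models and methods behind helixbend"
author: "helixbend authors"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind helixbend}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(helixbend)
```

# The scientific problem

A-form dsRNA is stiffer in bending than B-form dsDNA at physiological
monovalent salt, yet at very high salt (several molar NaCl or LiCl) the two
persistence lengths converge to a common intrinsic value near 39 nm.  The
mechanistic picture is electrostatic: the bending persistence length
decomposes into an electrostatic part, set by how completely bound ions
neutralize the phosphate backbone, and an intrinsic (non-electrostatic)
part that the two helical geometries happen to share.  helixbend implements
the complete desk-scale analysis chain for this comparison:

1. worm-like chain (WLC) fits of single-molecule force--extension records;
2. persistence lengths from bending-angle distributions of fixed-contour
   helix segments;
3. classification of ions into external (phosphate-shell) and internal
   (groove) binding shells with per-nucleotide charge fractions;
4. decomposition of the bending energy into electrostatic and intrinsic
   parts under a screened-Coulomb model;
5. axial groove-width and base-pair-inclination fluctuation analysis with
   Pearson correlations against the bending angle;
6. OSF and BJ fits of the salt dependence of the persistence length.

Since no instrument traces or simulation trajectories are distributed, a
seeded synthetic-data module generates every input the analyses need, with
published benchmark values (`referenceValues()`) as generator ground truth.
All tests and the acceptance script are therefore *round trips*: the
analyses must recover what the generators planted.

# Force--extension: the WLC interpolation with polynomial correction

The stretching force at extension $x$ of a chain with persistence length
$P$ and contour length $L_c$ is modelled as

$$F = \frac{k_BT}{P}\left[\frac{1}{4(1-x/L_c)^2} - \frac14 + \frac{x}{L_c}
  + \sum_{i=2}^{7}\alpha_i\left(\frac{x}{L_c}\right)^i\right],$$

the Marko--Siggia interpolation plus the seventh-order polynomial
correction of Bouchiat et al., which reduces the interpolation error to
below 0.01%.  The $\alpha_i$ are fixture constants
(`bouchiatCoefficients()`); the zero set (`markoSiggiaCoefficients()`)
recovers the plain interpolation for comparison.  `fitForceExtension()`
performs least squares on $(x, \log F)$ -- the logarithm keeps the
low-force tail from being swamped by the high-force points -- with bounded
Levenberg--Marquardt (P free, $L_c$ constrained above the largest observed
extension; starting values $P = 50$ nm, $L_c = 1.05\,\max x$).  Curves must
contain at least 8 points spanning a decade of force.

Units: $k_BT = 4.114$ pN nm at 298 K, scaled linearly in temperature.
Synthetic curves use 40 log-spaced forces over 0.05--30 pN with Gaussian
extension noise of $\sigma_x = 5$ nm, a realistic magnetic-tweezers noise
floor for a construct of $13\,751$ bp; the generator inverts the force law
by monotone root finding, so a noiseless round trip recovers $(P, L_c)$ to
relative $10^{-6}$.

```{r fx-example}
cu <- synthForceExtension(47, 0.34 * 13750, noise_x = 5, seed = 1)
fitForceExtension(cu, n_bp = 13751)
```

# Persistence length from bending-angle distributions

For a WLC segment of contour length $L_c$, the bending angle $\theta$
between the end tangents obeys

$$-\ln\left(\frac{p(\theta)}{\sin\theta}\right) =
  \frac{P\,\theta^2}{2L_c} + \text{const},$$

equivalently a bending energy $\Delta E_{bend}(\theta)/k_BT =
-\ln(p(\theta)/\sin\theta)$ that is quadratic with curvature $P/L_c$.
`fitPFromPdf()` bins angles at 0.5 degrees, regresses
$-\ln(p/\sin\theta)$ on $\theta^2/2L_c$ (radians) with the bin counts as
weights, and reports the slope as $P$.  Numerical choices:

* **Free intercept (default).**  The physical relation carries a
  normalization constant; fitting it as an intercept makes the slope
  independent of how $p$ is normalized.  `intercept = FALSE` is available
  for the literal zero-intercept form.
* **Fit range.**  Bins with fewer than 20 counts or beyond the 99th angle
  percentile are excluded: the log of a small count is noisy and biased.
* **Energy route.**  `bendingEnergy()` + `fitPFromEnergy()` implement the
  energy formulation on the same grid and agree with the pdf route
  exactly, by construction.

## Segment extraction and the effective contour length

`collectSegments()` pools every window of 13 bp (A-form) or 11 bp (B-form)
over all frames, excluding 3 terminal base pairs at each end.  Bending
angles come from the tangents of the two end base steps of the central
axis, where the axis smooths the base-pair centers with a 3-bp moving
average.  Those smoothed step tangents are chords spanning three raw steps,
which shortens the contour separating the two tangent estimates: with
linear smoothing weights the effective separation is exactly
$(n_{bp} - 2 - 8/9)$ steps.  `collectSegments()` therefore sets the
segment contour length to $(n_{bp} - 2 - 8/9)\times$ (the trajectory's own
mean rise), which makes the persistence fit an unbiased round trip against
the discrete-chain generator; with the naive $(n_{bp}-1)$ steps the fit
would run ~18% high.  This correction is a property of the tangent
estimator, not of the data.

## The trajectory generator

`sampleTrajectory()` builds each frame as a discrete worm-like chain:
every base step receives an independent bend drawn from
$p(\varphi)\propto\sin\varphi\,\exp(-P\varphi^2/2h)$ ($h$ = rise per bp)
about a uniformly random in-plane azimuth, composed with the canonical
twist.  Any fixed-length segment then has WLC bending statistics at the
configured $P$.  Angle sampling uses inverse-CDF interpolation on a
4096-point grid (adaptive upper limit, $\min(\pi, 8\sqrt{2L_c/P})$);
rejection sampling was rejected because its acceptance rate collapses for
stiff chains.  `bendHelix()` provides the complementary *controlled* bend:
a prescribed total angle distributed as a smooth arc over a window of steps
(default 9; window 1 gives a literal kink), with a per-step translation
correction that keeps the strand bonds crossing each hinge inextensible to
first order -- inter-phosphate distances change by well under 1% for bends
up to 30 degrees.

Idealized geometry constants (A-form: rise 0.28 nm, twist 32.7, resting
inclination +17 degrees; B-form: 0.34 nm, 34.3, -1 degree; phosphate-helix
radius 1.0 nm; axial groove fractions 0.25/0.75 of the pitch for A and
0.65/0.35 for B) are construction fixtures from standard fiber geometry,
not measured claims.

```{r angle-example}
ens <- sampleWlcAngles(55, 3.3, 2e5, seed = 7)
fitPFromPdf(angleHistogram(ens), 3.3)$P
```

# Ion binding shells

Ions are classified per frame with groove labels taking precedence:

* **internal** (major or minor groove): perpendicular distance to the
  local helical axis at most 8.5 A -- the ~10 A helical radius minus the
  ~1.5 A phosphate radius -- and azimuth inside the groove sector of the
  nearest base-pair frame.  The minor sector spans the arc between the two
  strands' phosphate azimuths; the major sector is the complement.
* **external**: not internal, and within 6 A of a phosphate atom (the
  second shell of the cation distribution around phosphates).
* **bulk** otherwise.

Charge fractions are signed sums (cations minus anions) per nucleotide,
averaged over frames with errors from four equal trajectory blocks.  The
generator plants Poisson-distributed shell occupancies, fills the box
(3 nm solvent margin) with bulk ion pairs at the configured concentration,
and neutralizes the remaining helix charge with a diffuse counterion
background that is explicitly excluded from the binding shells -- otherwise
the unbalanced counterions would bias the planted external fraction upward
by about 0.02 e/nt.  Distance searches are vectorised brute force, which
at desk scale (tens of phosphates, hundreds of ions) outperforms any
cell-list bookkeeping; the test oracles recompute them with explicit
per-ion loops.

# Electrostatic decomposition

The electrostatic bending energy uses a screened-Coulomb (linearized
Debye--Hueckel) model with uniform solvent dielectric 78:

$$E_{el} = l_B\sum_{i<j} q_i q_j \frac{e^{-\kappa r_{ij}}}{r_{ij}}
  \quad[k_BT],$$

with charges $-1e$ on the phosphorus sites (0 under the neutral-phosphate
flag) and $\kappa^{-1}$ the Debye length of the salt.  This replaces a
grid-based nonlinear Poisson--Boltzmann solver deliberately: the package's
contribution is the *decomposition*, which is solver-agnostic, and a PQR
writer (`writePQR()`) is provided so an external solver can be substituted.
The decomposition identities are exact:

$$\Delta E_{el}(\theta) = E_{el}(\theta) - E_{el}(0),\qquad
  \Delta E_{nel}(\theta) = \Delta E_{bend}(\theta) - \Delta E_{el}(\theta),$$

and each profile converts to a persistence length by the quadratic fit
above, so that for quadratic profiles $P = P_{el} + P_{nel}$ holds to
machine precision.  Because the surrogate model is not the full PB
calculation, the absolute $P_{el}$ scale (the published ~17 nm for dsRNA
versus ~10 nm for dsDNA) is a qualitative reference here, not a
recovered quantity; the package recovers the identities, the
neutral-phosphate limit ($P_{el} = 0$, $P_{nel} = P$), and the sign and
monotonicity of $\Delta E_{el}$.  The solute dielectric (8) is recorded in
the model object for PQR interoperability but unused by the screened
Coulomb form.

# Groove widths, inclination, and correlations with bending

*Axial* groove widths are measured along the helical axis: for each
strand-1 phosphate the strand-2 backbone is treated as a continuous helix
(axial position linearly interpolated against unwound azimuth), and the
minor width $d$ and major width $D$ are the axial gaps to the strand-2
crossings on either side.  On an ideal helix $D + d$ equals the pitch to
machine precision, which is the main structural invariant of the
implementation.  Base-pair inclination is the signed angle between the
base-pair long axis and the plane perpendicular to the local axis tangent.

`fluctuationProfile()` reports per-frame standard deviations along the
conformation (total groove width normalized per nm of contour);
`correlateWithBend()` computes Pearson correlations of these fluctuations
-- and of the per-frame means and fluctuations of the six simplified
base-step parameters (shift, slide, rise, tilt, roll, twist from a
symmetric mid-frame convention) -- with the whole-molecule bending angle.

Two planted-signal mechanisms in the generator exercise these analyses:

* **Inclination coupling.**  Per-base-pair inclination jitter whose
  amplitude grows with the frame's bend
  ($\sigma(1 + \beta\theta)$).  With $\sigma = 3$ degrees and
  $\beta = 1$ rad$^{-1}$ the measured correlation is 0.40, calibrated once
  against the benchmark correlation scale and frozen; the coupling itself
  mimics the geometric fact that bends toward the major and minor grooves
  raise and lower inclination, which `bendHelix()` plants explicitly at
  its pivot (a rigid coarse-site kink leaves inclination unchanged to
  first order, so the generator must encode the coupling rather than
  derive it).
* **Total-width coupling.**  Axial jitter of the *strand-2* phosphates
  only: displacing strand 2 along the axis moves the minor and major gaps
  of nearby positions in the same direction (strand-1 jitter would move
  $d$ and $D$ oppositely and cancel in $D + d$).  With bend-coupled
  amplitude this reproduces the qualitative hierarchy: the total-width
  fluctuation correlates more strongly with bending than the major width
  alone, which beats the minor width alone.

What passing these tests shows -- and does not show -- about real data:
the analyses recover planted signals of realistic size from realistically
noisy synthetic conformations.  They do not show that real trajectories
contain such signals; the generator has no sequence dependence, no
all-atom detail, no water, and plants couplings that in nature emerge from
the force field.

# Salt dependence: OSF and BJ models

The monovalent-salt dependence of the persistence length is fitted with
two standard polyelectrolyte forms,

$$P_{OSF}(c) = P_{nel} + \frac{l_B}{4\kappa^2 b^2}
  \quad(\propto 1/c),\qquad
  P_{BJ}(c) = P_{nel} + A\,\kappa^{-1}\quad(\propto c^{-1/2}),$$

by weighted least squares (weights $1/\mathrm{SE}^2$), with amplitudes
bounded at zero.  Both are linear in their parameters given the predictor,
so the fits are exact on noiseless data.  The BJ form, with its softer
$c^{-1/2}$ decay, is the one that tracks high-precision data up to molar
salt; the package compares the two by residual sum of squares.  The BJ
scaling form with a free amplitude is used because the literature offers
several variational variants; the free amplitude absorbs that ambiguity.

# The pipeline and reproducibility

`runPipeline()` chains all stages on synthetic inputs and writes one CSV
per stage plus a JSON manifest of every parameter.  All randomness flows
from the configuration seed through derived per-stage streams, so
identical configurations give byte-identical outputs and disabling one
stage leaves the others' tables unchanged.  Default problem sizes --
10 molecules per salt condition for force--extension, 600 frames of a
20-bp duplex for the trajectory stages, $2\times10^5$ angles for direct
ensemble fits -- were chosen so each analysis resolves its target to a few
percent; the statistical tests in the package run at 1 200 to 12 000
frames, sizes at which the planted effects exceed their standard errors
three-fold or more.  The 1 M persistence-length entries in the default
condition table are BJ-interpolated between the 150 mM and 4 M benchmarks,
since only those two concentrations have published point values.

# Known limitations

* Coarse sites only (phosphates, base-pair triads): no sequence effects,
  backbone torsions or sugar puckers, and the "neutral" construct is
  emulated by zeroing phosphate charges rather than editing per-atom
  partial charges.
* The screened-Coulomb surrogate underestimates the absolute electrostatic
  bending energy of a fully charged duplex; quantitative $P_{el}$ values
  require an external PB solver via the PQR export.
* The axial groove-width algorithm assumes strands wind monotonically;
  conformations bent beyond ~60 degrees over a few steps can lose
  crossings near the ends (dropped with a warning).
* Twist and stretch elasticity, and twist-stretch coupling, are out of
  scope.
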