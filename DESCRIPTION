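Package: helixbend
Title: Bending Stiffness Analysis for Double-Stranded RNA and DNA
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Desk-scale analysis of the bending stiffness of double-stranded
    RNA (A-form) and DNA (B-form) helices. Implements worm-like chain (WLC)
    force-extension fitting with the seventh-order polynomial correction to
    the Marko-Siggia interpolation, persistence-length estimation from
    bending-angle distributions of fixed-contour-length helix segments,
    classification of bound ions into external (phosphate-shell) and internal
    (major/minor groove) shells with per-nucleotide charge fractions,
    decomposition of the bending energy into electrostatic and intrinsic
    parts under a screened-Coulomb (Debye-Hueckel) model, axial groove-width
    and base-pair-inclination fluctuation analysis with Pearson correlations,
    and Odijk-Skolnick-Fixman / Barrat-Joanny fits of the salt dependence of
    persistence length. A seeded synthetic-data generator supplies WLC angle
    ensembles, noisy force-extension traces, and idealized bent helices with
    ion atmospheres, standing in for the instrument and the molecular
    dynamics engine.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports: methods, stats, utils, minpack.lm, jsonlite
Suggests: testthat (>= 3.0.0), withr, knitr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
Roxygen: list(markdown = TRUE)
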