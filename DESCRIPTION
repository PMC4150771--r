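Package: quadrepair
Title: Hydrodynamics, Binding Stoichiometry and Repair Kinetics of
    O6-Methylguanine in Telomeric G-Quadruplex DNA
Version: 1.0.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Quantitative analysis chain for O6-alkylguanine-DNA
    alkyltransferase (AGT) acting on human-telomere G-quadruplex DNA:
    buffer-corrected sedimentation coefficients (s20,w) with Perrin
    prolate-ellipsoid shape inversion, global multi-speed
    sedimentation-equilibrium fitting of AGT:DNA binding stoichiometry,
    a finite-volume Lamm-equation solver with Tikhonov-regularized c(S)
    inversion, biphasic repair-kinetics fitting with F-test phase-count
    selection, and two-state van 't Hoff analysis of CD melting curves.
    A seeded synthetic-data generator emulates every instrument input so
    the whole chain runs, and is validated by parameter recovery,
    without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    minpack.lm,
    pracma,
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
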