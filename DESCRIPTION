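Package: arterymech
Title: Multiscale Hypoelastic Finite-Element Simulation of Arterial Tension-Inflation Tests
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Simulates the mechanical and microstructural response of arterial
    segments under tension-inflation loading with a multiscale hypoelastic
    constitutive model. The adventitia is described as a matrix reinforced by
    crimped collagen fiber families: fiber de-crimping follows a sinusoidal
    crimped-beam chord-modulus model, and non-affine fiber rotation follows
    Eshelby/Mori-Tanaka mean-field homogenization with strain-rate and spin
    concentration tensors. The macroscopic problem is solved by an explicit
    incremental (forward-Euler, staggered) finite-element scheme on hexahedral
    meshes of the two-layer hollow cylinder, with follower pressure loads.
    Includes case-study drivers for inflation tests at constant stretch,
    tension tests at constant pressure, collagen-disorder sweeps and
    shear-stiffness readouts, plus a single material-point driver for
    homogeneous deformation paths.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Matrix,
    Rcpp,
    stats,
    tibble,
    utils
Suggests:
    testthat (>= 3.0.0),
    ggplot2,
    jsonlite,
    yaml,
    optparse
Config/testthat/edition: 3
LinkingTo:
    Rcpp
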