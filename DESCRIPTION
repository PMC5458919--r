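Package: porehydro
Title: Hydrodynamics of Water Transport Through Hourglass-Shaped Nanopores
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Analysis of pressure-driven water transport through
    hourglass-shaped (biconical) nanopores of aquaporin-like dimensions.
    Implements the analytical hydrodynamic-resistance model combining a
    Sampson-type access term with a slip-corrected Poiseuille integral over
    the conical vestibules, an axisymmetric Stokes solver for the
    dimensionless access-resistance factor under Navier partial slip,
    osmotic-permeability estimation, trajectory statistics for single-file
    water transport (axial density profiles, adjacent-gap "shooting"
    analysis, crossing-flux counting), and a seeded phenomenological
    trajectory generator for exercising the analysis stages end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    Matrix,
    jsonlite,
    yaml,
    stats,
    utils
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
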