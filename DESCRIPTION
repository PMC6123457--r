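Package: deptrap
Title: Dielectrophoretic Single-Cell Trapping Simulator for Ring-Electrode
    Microfluidic Devices
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Physics simulator for negative-dielectrophoresis (nDEP)
    single-cell trapping on ring-shaped microelectrode arrays inside a
    microfluidic channel.  Implements frequency-domain dielectric response
    (complex permittivities, the Clausius-Mossotti factor, the single-shell
    cell model, crossover frequencies), a finite-difference solver for the
    axisymmetric electro-quasistatic potential of a ring trap electrode,
    the time-averaged dipolar DEP force, and overdamped particle-trajectory
    integration with Stokes drag, plane-Poiseuille channel flow and buoyant
    gravity.  A declarative experiment runner simulates seeded particle
    ensembles, classifies trapping outcomes, and exports trajectory, field
    and spectrum tables.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    Matrix,
    jsonlite,
    stats,
    tools,
    utils,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
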