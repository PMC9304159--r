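Package: oxoscope
Title: Post-Processing of Quantum-Chemistry Results for Nonheme Iron-Oxo
    Selectivity Studies
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for the analysis layer that sits downstream of electronic
    structure calculations on enzymatic C-H activation: rigid-rotor
    harmonic-oscillator thermochemistry from frequencies or Cartesian
    Hessians, composite energy assembly, isotope-substitution frequency
    shifts, transition-state-theory rates, Eyring and Wigner-corrected
    kinetic isotope effects, Boltzmann branching and selectivity verdicts
    over multi-pathway reaction landscapes, bond dissociation free energies
    under uniform external electric fields, and point-charge electrostatics
    (residue census, dipole, local field) of protein structures. Includes
    seeded synthetic generators for every input class so that the full
    pipeline can be exercised against known ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    bio3d,
    stats,
    utils,
    yaml
Suggests:
    jsonlite,
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
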