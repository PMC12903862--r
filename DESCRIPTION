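Package: alchemfe
Title: Alchemical Free-Energy Calculations with Softcore Many-Body Potentials
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for alchemical free-energy calculations with machine-learned
    and model interatomic potentials. Constructs softcore short-range dimer
    curves by matching an a*r^10 + b force polynomial at an automatically
    selected switching point, implements lambda-scaled decoupling of two-body
    features in an invariant body-ordered potential, Beutler softcore
    Lennard-Jones interactions, Langevin (BAOAB) dynamics with a Monte Carlo
    barostat, Hamiltonian replica exchange over a lambda schedule, and free
    energy estimation by thermodynamic integration, BAR and MBAR with automated
    equilibration detection and decorrelation. Includes an end-to-end solvation
    free-energy and log P pipeline plus synthetic fixture generators (analytic
    dimers, harmonic lambda families, Gaussian work models, small
    Lennard-Jones fluids) with closed-form answers.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    jsonlite,
    stats,
    utils,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr,
    bio3d
Config/testthat/edition: 3
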