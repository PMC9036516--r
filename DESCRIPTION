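Package: ecrism
Title: Embedded-Cluster Reference Interaction Site Model for Solvation Free Energies
Version: 0.1.0
Authors@R:
    person("Pkg", "Maintainer", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Integral-equation solvation modelling in water: dielectrically
    consistent 1D-RISM for the bulk-solvent site-site susceptibility, a 3D-RISM
    solver with KH/PLHNC/PSE-n/HNC closures and MDIIS acceleration, excess
    chemical potential functionals with pressure (PC/PC+) and universal (UC)
    corrections, electrostatic-potential (CHELPG-style) charge fitting, solvent
    point-charge extraction with thresholding, and the self-consistent
    embedded-cluster coupling loop between a quantum-chemistry backend and the
    RISM solvent. A closed-form polarizable mock engine stands in for real
    quantum chemistry so the whole pipeline is testable offline.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
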