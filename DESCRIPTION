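Package: eemcc
Title: Energy-Entropy Multiscale Cell Correlation Free-Energy Analysis
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Total free-energy analysis of hydrated biomolecules from
    molecular dynamics trajectories carrying coordinates, atomic forces and
    per-atom energies. Entropy is computed with the multiscale cell
    correlation (MCC) method: quantum-harmonic-oscillator vibrational
    entropy from mass-weighted force and inertia-weighted torque covariance
    matrices at united-atom, residue and whole-molecule levels;
    conformational (topographical) entropy from dihedral conformer
    distributions; and water orientational entropy from hydrogen-bond
    donor/acceptor statistics over parameter-free relative-angular-distance
    (RAD) coordination shells. Enthalpy is partitioned from per-atom
    potential and kinetic energies, and free energy assembled as G = H - TS
    per water molecule, residue and molecule, with grouping, referencing and
    correlation reports. Includes seeded synthetic-trajectory generators
    (Boltzmann harmonic samplers, idealized water boxes, a toy dipeptide)
    with analytic ground truth for validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    bio3d,
    jsonlite,
    stats,
    utils,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
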