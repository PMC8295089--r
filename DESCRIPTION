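Package: eemcc
Title: Energy-Entropy Multiscale Cell Correlation for Absolute Entropies and
    Octanol-Water logP from Molecular Dynamics
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Computes absolute entropies, transfer free energies and
    octanol-water partition coefficients (logP) from molecular-dynamics
    trajectories that carry forces. Entropy is decomposed multiscale over
    molecule and united-atom levels into vibrational terms (quantum harmonic
    oscillator entropies from mass-weighted force and inertia-weighted torque
    covariance matrices) and topographical terms (positional, orientational
    via coordination-number statistics from Relative Angular Distance
    solvation shells, and conformational via a dihedral-conformer correlation
    matrix). Includes readers for a minimal AMBER prmtop subset and a
    plain-text fixture trajectory dialect, and a synthetic-system generator
    (harmonic liquids, multi-state dihedral series, toy shell geometries)
    with analytically known entropies for validation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    yaml,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr,
    jsonlite
Config/testthat/edition: 3
RoxygenNote: 7.3.3
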