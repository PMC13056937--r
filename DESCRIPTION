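Package: nmadielectric
Title: Sub-Terahertz Dielectric Spectra from Protein Normal Modes
Version: 0.1.0
Authors@R: person("Package", "Maintainer", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Computes complex dielectric susceptibility, permittivity,
    extinction and absorption spectra in absolute units from normal-mode
    frequencies, mass-weighted Cartesian eigenvectors and per-atom partial
    charges, using a damped Lorentz-oscillator model with orientational
    averaging. Supports decomposition of mode dipole variations into
    protein, water and ligand components, inter-component dipole angles,
    vibrational density of states histograms, hydration-shell persistence
    statistics from shell-assignment trajectories, and dilute-mixing
    corrections for bound water. Includes a generator of small synthetic
    harmonic systems with analytic Hessians and Markov-chain water-shell
    trajectories that serve as exactly solvable test oracles.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
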