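# nmadielectric

Sub-terahertz dielectric spectra of proteins from normal-mode analysis.

Proteins in solution have collective vibrations in the 10–1000 GHz
range. Because the atoms carry partial charges, each normal mode has a
dipole derivative and absorbs microwave/sub-THz radiation. This package
takes normal-mode output — mode frequencies, mass-weighted Cartesian
eigenvectors, per-atom masses and charges — and computes the resulting
dielectric response in absolute units, for people modelling protein
electrodynamics or interpreting sub-THz absorption measurements.

The core is a damped Lorentz-oscillator sum. For mode *l* with frequency
ν<sub>l</sub> (Hz), damping γ, and mass-weighted effective charge
ρ<sub>l</sub> = ‖Σ<sub>i</sub> q<sub>i</sub> **e**<sub>l,i</sub>‖
(eigenvectors in kg<sup>−1/2</sup>):

    χ(ν) = (1/3) · N_V/(4π²ε₀) · Σ_l ρ_l² / (ν_l² − ν² − j ν γ)

with N<sub>V</sub> the molecular number density. From χ = χ′ + jχ″:
ε_r′ = 1 + ε<sub>∞</sub> + χ′, ε_r″ = χ″, extinction
k = √(½(−ε_r′ + √(ε_r′² + ε_r″²))), absorption α = 4πν k/c (m⁻¹).

Beyond spectra, the package decomposes mode dipoles into protein / water
/ ligand components (which add vectorially but not in intensity —
partial cancellation of transition dipoles), computes inter-component
dipole angles and per-residue displacement profiles, bins a vibrational
density of states, measures hydration-shell persistence in
shell-assignment trajectories, and applies a dilute-mixing correction
for bound water removed from the bulk solvent response. A synthetic
module generates bead–spring systems with analytic Hessians and
Markov-chain shell trajectories, so every operation is testable against
closed forms.

## Worked example

A 10-bead random elastic network ("protein"), hydrated with 6 stiffly
tethered water beads, solved exactly and pushed through the pipeline at
0.5 mM (19 mg/mL for a 38 kg/mol protein):

```r
library(nmadielectric)

core     <- build_harmonic_system("random", n_atoms = 10, seed = 1)
hydrated <- synth_hydrated_variant(core, n_shell_particles = 6,
                                   attach_stiffness = 2, seed = 2)
modes <- select_vibrational_modes(solve_modes(hydrated))
modes
#> <mode_set> 42 modes over 16 atoms; frequencies 34.79 to 3684 GHz

dip <- mode_dipole(modes, "whole")
params <- lorentz_params(gamma_hz = 10e9,
  number_density = concentration_conversions(0.5e-3, 38)$number_density_m3)
spec <- dielectric_spectrum(dip, params, seq(1e9, 1000e9, by = 1e9))
spec
#> <dielectric_spectrum> 1000 points, 1-1000 GHz, max alpha = 560.6 1/m
```

The peak absorption is 560.6 m⁻¹ at 96 GHz — the softest charged modes
of this toy dominate the sub-THz band. Hydration stiffens the composite:

```r
bare <- select_vibrational_modes(solve_modes(core))
c(bare$frequencies[1], modes$frequencies[1]) / 1e9
#> 10.3  34.8   # GHz: the lowest vibration blue-shifts
```

Bound-water accounting at the highest experimental concentration
(1124 bound waters per protein, 0.517 mM, user-supplied water
permittivity at 100 GHz):

```r
mixing_estimate(1124, 0.517e-3, water_eps_real = 8.9,
                water_eps_imag = 13.9, nu_hz = 100e9,
                molar_mass_kg_mol = 38)
#> <mixing_estimate> n_b = 1124, c = 0.517 mM -> f_rm = 1.05%
#>   delta chi' = -0.0829, delta chi'' = -0.146, delta alpha = -45.6 1/m at 100 GHz
```

f_rm = 1.05 % of the solvent water is sequestered in 3 Å shells; the
bulk response drops proportionally.

Real normal-mode ensembles enter through
`read_mode_ensemble(frequency_xvgs, eigenvector_tsvs, atom_tsv)` (XVG
frequencies in cm⁻¹, tab-separated eigenvectors, companion atom
metadata, optional GRO/PDB coordinates); `run_pipeline()` /
`nmadielectric_cli()` drive the whole chain from a config file and write
TSV tables plus a manifest.

## Layout

- `R/` — atoms/modes containers and IO, synthetic harmonic systems,
  dipoles, Lorentz spectra, hydration shells, bound-water mixing, CLI.
- `tests/testthat/` — unit + property tests per module;
  `test-acceptance.R` holds the acceptance criteria.
- `vignettes/nma-dielectric-methods.Rmd` — the model, its assumptions,
  parameter defaults, numerical choices, and what the synthetic oracles
  do and do not establish.
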