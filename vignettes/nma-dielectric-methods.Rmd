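---
title: "Methods: from normal modes to sub-THz dielectric spectra"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: from normal modes to sub-THz dielectric spectra}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

## The model

A protein at a potential-energy minimum vibrates in normal modes: the
eigenvectors of the mass-weighted Hessian, with harmonic frequencies
$\nu_l = \sqrt{\lambda_l}/2\pi$. Each mode carries a time-varying dipole
moment because its atoms carry partial charges, so it couples linearly to
an external electric field. In linear response, with a phenomenological
damping rate $\gamma_l$ and an isotropic orientational average (factor
$1/3$), the vibrational contribution to the complex dielectric
susceptibility of a solution with molecular number density $N_V$ is the
Lorentz-oscillator sum

$$\chi(\nu) = \frac{1}{3}\frac{N_V}{4\pi^2\varepsilon_0}
  \sum_{l=1}^{M} \frac{\rho_l^2}{\nu_l^2 - \nu^2 - j\,\nu\,\gamma_l},$$

where the oscillator strength of mode $l$ is its mass-weighted effective
charge (dipole derivative)

$$\rho_l = \Bigl\| \sum_i q_i\, \mathbf{e}_{l,i} \Bigr\|,$$

with $q_i$ the partial charges (stored in C) and $\mathbf{e}_{l,i}$ the
Cartesian eigenvector components in $\mathrm{kg}^{-1/2}$ (orthonormal in
the mass metric, $\sum_i m_i \mathbf{e}_{l,i}\!\cdot\!\mathbf{e}_{l',i} =
\delta_{ll'}$). Splitting real and imaginary parts with
$A_l = \nu_l^2 - \nu^2$ and $B_l = \nu\gamma_l$ gives the implemented
forms; `susceptibility()` computes both the split and the complex route
and they agree to machine precision (a tested invariant). Dimensionally,
$\rho^2$ carries $\mathrm{C^2\,kg^{-1}}$, and
$N_V \rho^2 / (\varepsilon_0 \nu^2)$ is dimensionless, so $\chi$ is too.

The relative permittivity is $\varepsilon_r = 1 + \varepsilon_\infty +
\chi' + j\chi''$, the extinction coefficient follows from
$\tilde n^2 = \varepsilon_r$ as
$k = \sqrt{\tfrac12(-\varepsilon_r' + \sqrt{\varepsilon_r'^2 +
\varepsilon_r''^2})}$, and the absorption coefficient is
$\alpha = 4\pi\nu k / c$ in $\mathrm{m^{-1}}$.

Assumptions inherited by everything downstream: linear response,
independent modes (no mode coupling), a single phenomenological $\gamma$
(a per-mode vector is accepted by the data model but not the defaults),
isotropic orientations, and dilute non-interacting molecules. Component
decomposition (protein vs water vs ligand) restricts the *charge sum*
only — the eigenvectors remain those of the whole coupled system — so
component dipole vectors add exactly, and the law of cosines
$\rho_{\rm whole}^2 = \rho_p^2 + \rho_w^2 + 2\rho_p\rho_w\cos\theta$
quantifies any non-additivity of component spectra.

## Parameters that matter

| parameter | units | default | why |
|---|---|---|---|
| damping $\gamma$ | Hz | $10^{11}$ (100 GHz) | middle of the swept decade 10–10,000 GHz; underdamped to overdamped |
| number density $N_V$ | m$^{-3}$ | from molarity, $c \cdot 1000 N_A$ | 0.5 mM $\to 3.011\times10^{23}$ |
| $\varepsilon_\infty$ | — | 0 | vibrational response only; option $\approx 2$ for an electronic $n^2$ background |
| frequency grid | Hz | 1–2000 GHz, 1 GHz steps | covers the sub-THz window with margin |
| zero tolerance | Hz | 1 GHz | separates rigid-body modes from the softest genuine vibrations |
| shell boundaries | Å | 0, 3, 5, 7, 9 | standard hydration bands; 0–3 Å defines bound water |
| persistence threshold | ps | 20 | one frame interval at the 20 ps trajectory spacing |
| water molarity | mol/L | 55.345 | 0.997 g/mL at 25 °C / 18.015 g/mol; reproduces the 0.0203 per-mM coefficient to 3 s.f. |

Physical constants are CODATA-2018, fixed in `physical_constants()`.
Frequencies are linear ($\nu$, Hz) throughout, never angular; wavenumber
input is converted with the exact factor $2.99792458\times10^{10}$.

## What the synthetic generator emulates — and what it does not

`build_harmonic_system()` makes bead–spring toys whose springs have zero
force at the generated geometry, so the analytic Hessian (per-spring
block $k\,\hat n \hat n^\top$) is exact and no minimizer is involved.
Central-force networks are only rigid when they have enough
well-distributed springs; the `random` topology densifies shortest edges
until the mass-weighted Hessian has exactly six near-zero eigenvalues,
while `chain`/`ring` exist for closed-form oracles (reduced-mass
diatomic, trace identity) and may be floppy. Default bead masses (12
amu), charges (±0.4 e) and stiffness (0.02 N/m) put the spectra in the
100 GHz region a protein's softest modes occupy.

The hydrated variant tethers water-mass beads to their **five** nearest
core atoms. This number is a deliberate design choice: with three
tethers, the stiff limit merely slaves the bead's three degrees of
freedom and adds pure mass, red-shifting the spectrum; each tether
beyond the third bridges core atoms through the bead and stiffens the
composite, the way a water molecule hydrogen-bonded to several surface
atoms couples them. With five anchors the hydration blue-shift of the
lowest vibrational band is robust across tether stiffnesses from equal
to 1000× the core springs.

The shell-persistence generator is a first-order Markov chain with a
known stay probability — exactly the null model the persistence
estimator should recover, and nothing more.

What a green test therefore establishes: the algebra of the pipeline
(eigensolution, dipole sums, Lorentz sums, unit bookkeeping, persistence
counting) is correct against independent closed forms. What it does not
establish: anything about real force fields, anharmonicity, mode-overlap
across replicas, polarizability, or the absolute spectra of real
proteins, which require deposited normal-mode data this package reads
but does not ship.

Angle statistics on synthetic toys carry one structural caveat worth
knowing: vibrational eigenvectors are momentum-orthogonal to the
translations ($\sum_i m_i\mathbf e_{l,i}=0$), so with uniform same-sign
charges the two components' charge-weighted sums oppose each other
exactly. The antiparallel-bias test uses this construction; real systems
show the milder, mode-dependent version of the same cancellation.

## Numerical choices

- **Rigid-body modes.** The six smallest-$|\nu|$ modes below the zero
  tolerance are removed before the "first $M$ modes" truncation (a
  $\nu_l \to 0$ Lorentz term would diverge). If fewer than six lie below
  tolerance — a linear toy has five — only those are removed, with a
  warning; unconditionally deleting six would destroy the diatomic's
  stretch mode.
- **Imaginary frequencies.** Negative eigenvalues beyond a relative
  tolerance of $10^{-9}$ (and negative-frequency markers on file input)
  are errors, signalling an incomplete minimization, never silently
  dropped.
- **Degeneracy.** Eigenvector bases inside degenerate multiplets are
  arbitrary; tests assert sums over multiplets or basis-invariant
  quantities ($\rho^2$ totals, law of cosines), never individual
  degenerate columns.
- **Angles.** $\cos\theta$ is clamped to $[-1,1]$ before `acos`; modes
  with a zero-magnitude component vector get `NA`, are excluded from
  ensemble means and reported as a count.
- **Kramers–Kronig check.** The principal-value integral is evaluated by
  trapezoid quadrature with symmetric exclusion of the singular grid
  point; on a dense grid spanning 0.01–100× the resonance it
  reconstructs $\chi'$ to $\sim 10^{-6}$ relative, validating the
  spectral numerics (the Lorentz form is KK-consistent analytically).
- **Ensemble averaging** is applied to every derived quantity
  independently ($\chi$, $\varepsilon$, $k$, $\alpha$), since averaging
  and the nonlinear $\alpha(\varepsilon)$ map do not commute; both means
  are available for inspection.
- **Binning.** VDOS bins are half-open $[e, e+\Delta)$ so no mode is
  double-counted; counts conserve mode number exactly; the normalization
  $g_n = n_j/(N_f\Delta\omega)$ collapses system sizes in the
  low-frequency regime where the raw density scales like $N_f\,\nu$.

## Bound-water accounting

A 3 Å shell defines bound water; `count_bound_waters()` uses the
minimum distance from each water reference point (an oxygen-like single
bead; switchable to heavy-atom-only protein distances) to any protein
atom. The removed-water fraction $f_{\rm rm} = n_b c / c_{\rm water}$ is
exactly linear in both arguments; dilute linear mixing then reduces the
solvent response by $\Delta\chi' = -f_{\rm rm}(\varepsilon_w' - 1)$,
$\Delta\chi'' = -f_{\rm rm}\varepsilon_w''$, with $\Delta\alpha$
recomputed through the extinction relation. Water permittivities are
caller-supplied: the package bundles no water model, and the comparison
against reported $\Delta$ estimates is a soft check because the
underlying $\varepsilon_w$ values live in cited literature, not in any
shipped table. The shell-overlap concentration uses bare sphere volumes
(no packing correction); at the documented 2.1 nm radius it returns
1.09 g/mL, and an effective radius near 3.1 nm is what places the
threshold in the often-quoted 0.3–0.5 g/mL band — the function is kept
geometric and the radius is the user's modelling decision.

## Known limitations

Harmonic, single-minimum dynamics only; no Maxwell–Garnett/Bruggeman
mixing (the dilute linear correction is the only solvent coupling); no
periodic-boundary minimum-image handling (real trajectories must be
pre-wrapped); replica mode matching is by frequency rank, which scrambles
physically-corresponding modes when bands cross; and the GRO/PDB readers
ingest coordinates only — topology, masses and charges travel in the
companion TSV.
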