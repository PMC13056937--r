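# Fixture builders used across the suite. Everything is generated in
# code; no stored data files.

K <- physical_constants()

# Diatomic chain along x: the minimal closed-form system.
fix_diatomic <- function(m1 = 12, m2 = 12, q = 0.4, k = 0.02) {
  build_harmonic_system("chain", 2, masses_amu = c(m1, m2),
                        charges_e = c(q, -q), spring_constant = k, seed = 1)
}

# Vibrational modes of a diatomic (one stretch mode).
fix_diatomic_modes <- function(...) {
  suppressWarnings(select_vibrational_modes(solve_modes(fix_diatomic(...)),
                                            zero_tolerance_hz = 1e10))
}

# Rigid random network with protein/water component labels.
fix_mixed_network <- function(n = 10, seed = 1, n_water = 3) {
  comp <- c(rep("protein", n - n_water), rep("water", n_water))
  build_harmonic_system("random", n, component = comp, seed = seed)
}

# A one-mode dipole table with prescribed frequency and magnitude, for
# closed-form spectral checks.
fix_single_mode <- function(nu_hz = 100e9, rho = 1e-21) {
  structure(list(component = "custom",
                 vectors = rbind(x = rho, y = 0, z = 0),
                 magnitudes = rho, frequencies = nu_hz),
            class = "dipole_table")
}

# Hand-built 4-atom mode set with a single prescribed eigenvector,
# mass-normalized so the orthonormality check passes.
fix_handmade_modeset <- function(cart_ev, masses_amu = rep(12, 4),
                                 charges_e = c(0.4, -0.4, 0.3, -0.3),
                                 component = rep("protein", 4),
                                 residue_index = c(1, 1, 2, 2),
                                 freq_hz = 1e11) {
  atoms <- atom_set(masses_amu, charges_e, component = component,
                    residue_index = residue_index)
  w <- rep(atoms$masses, each = 3)
  ev <- cart_ev / sqrt(sum(w * cart_ev^2))   # normalize in mass metric
  mode_set(atoms, freq_hz, matrix(ev, ncol = 1))
}
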