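test_that("mode_dipole: zero charges, symmetric cancellation, closed form", {
  # all charges zero -> rho identically 0
  sys0 <- build_harmonic_system("random", 6, charges_e = 0, seed = 2)
  d0 <- mode_dipole(select_vibrational_modes(solve_modes(sys0)))
  expect_identical(max(d0$magnitudes), 0)
  # homonuclear diatomic with equal charges: stretch dipole cancels
  sym <- build_harmonic_system("chain", 2, masses_amu = c(12, 12),
                               charges_e = c(0.4, 0.4), seed = 1)
  vs <- suppressWarnings(select_vibrational_modes(solve_modes(sym),
                                                  zero_tolerance_hz = 1e10))
  expect_lt(mode_dipole(vs)$magnitudes, 1e-20 * 0.4 * K$e_charge)
  # +q/-q equal-mass diatomic: rho = q * sqrt(2/m)
  vib <- fix_diatomic_modes(12, 12, q = 0.4)
  rho <- mode_dipole(vib)$magnitudes
  expect_equal(rho, 0.4 * K$e_charge * sqrt(2 / (12 * K$amu)),
               tolerance = 1e-10)
  expect_error(mode_dipole(vib, integer(0)), "empty")
  expect_error(mode_dipole(vib, 99), "outside")
})

test_that("component dipole vectors are additive and obey the law of cosines", {
  sys <- fix_mixed_network(10, seed = 5, n_water = 4)
  vib <- select_vibrational_modes(solve_modes(sys))
  dw <- mode_dipole(vib, "whole")
  dp <- mode_dipole(vib, "protein")
  da <- mode_dipole(vib, "water")
  # exact additivity over the partition (no ligand atoms here)
  expect_equal(dw$vectors, dp$vectors + da$vectors, tolerance = 1e-15)
  # law of cosines per mode: the quantitative form of non-additivity
  th <- component_angles(dp, da)$angles_deg * pi / 180
  lhs <- dw$magnitudes^2
  rhs <- dp$magnitudes^2 + da$magnitudes^2 +
    2 * dp$magnitudes * da$magnitudes * cos(th)
  expect_equal(lhs, rhs, tolerance = 1e-12)
})

test_that("rho is invariant under rigid rotation of the whole system", {
  sys <- fix_mixed_network(8, seed = 6, n_water = 2)
  vib <- select_vibrational_modes(solve_modes(sys))
  th <- 0.83
  R <- matrix(c(cos(th), -sin(th), 0, sin(th), cos(th), 0, 0, 0, 1), 3, 3,
              byrow = TRUE)
  n <- vib$atoms$n_atoms
  rot <- kronecker(diag(n), R)
  ev_rot <- rot %*% vib$eigenvectors
  atoms_rot <- vib$atoms
  atoms_rot$coordinates <- vib$atoms$coordinates %*% t(R)
  ms_rot <- mode_set(atoms_rot, vib$frequencies, ev_rot)
  expect_equal(mode_dipole(ms_rot)$magnitudes, mode_dipole(vib)$magnitudes,
               tolerance = 1e-12)
})

test_that("component_angles handles parallel, antiparallel and a 120-degree toy", {
  sys <- fix_mixed_network(10, seed = 5, n_water = 4)
  vib <- select_vibrational_modes(solve_modes(sys))
  a <- mode_dipole(vib, "protein")
  self <- component_angles(a, a)$angles_deg       # acos round-off only
  expect_true(all(abs(self[!is.na(self)]) < 1e-4))
  b <- a
  b$vectors <- -a$vectors
  anti <- component_angles(a, b)$angles_deg
  expect_true(all(abs(anti[!is.na(anti)] - 180) < 1e-4))
  # hand-built vectors at 120 degrees
  va <- a; vb <- a
  va$vectors <- matrix(c(1, 0, 0), 3, length(a$magnitudes))
  va$magnitudes <- sqrt(colSums(va$vectors^2))
  vb$vectors <- matrix(c(-0.5, sqrt(3) / 2, 0), 3, length(a$magnitudes))
  vb$magnitudes <- sqrt(colSums(vb$vectors^2))
  expect_equal(component_angles(va, vb)$angles_deg,
               rep(120, length(a$magnitudes)), tolerance = 1e-10)
  # zero-magnitude vectors are undefined, not zero
  vb$vectors[, 1] <- 0
  vb$magnitudes[1] <- 0
  ang <- component_angles(va, vb)
  expect_true(is.na(ang$angles_deg[1]))
  expect_identical(ang$n_undefined, 1L)
  short <- a
  short$vectors <- a$vectors[, -1, drop = FALSE]
  short$magnitudes <- a$magnitudes[-1]
  expect_error(component_angles(a, short), "mode-count mismatch")
})

test_that("ensemble_angle_profile averages by frequency rank", {
  sys <- fix_mixed_network(10, seed = 5, n_water = 4)
  vib <- select_vibrational_modes(solve_modes(sys))
  ens1 <- mode_ensemble(list(vib))
  single <- ensemble_angle_profile(ens1, "protein", "water", n_modes = 5)
  direct <- component_angles(mode_dipole(vib, "protein"),
                             mode_dipole(vib, "water"))$angles_deg[1:5]
  expect_equal(single$mean_deg, direct)
  expect_identical(max(single$sd_deg), 0)
  # two replicas: plain two-point mean per rank
  sys2 <- fix_mixed_network(10, seed = 9, n_water = 4)
  vib2 <- select_vibrational_modes(solve_modes(sys2))
  ens2 <- mode_ensemble(list(vib, vib2))
  prof <- ensemble_angle_profile(ens2, "protein", "water", n_modes = 5)
  d2 <- component_angles(mode_dipole(vib2, "protein"),
                         mode_dipole(vib2, "water"))$angles_deg[1:5]
  expect_equal(prof$mean_deg, (direct + d2) / 2)
  expect_error(ensemble_angle_profile(ens2, n_modes = 1e6), "exceeds")
})

test_that("antiparallel-biased construction gives obtuse mean angles", {
  # vibrational modes are momentum-orthogonal to the translations,
  # sum_i m_i e_{l,i} = 0, so with uniform same-sign charges the two
  # components' charge-weighted sums necessarily oppose each other:
  # the component dipoles are antiparallel-biased by construction
  angs <- lapply(1:3, function(s) {
    core <- build_harmonic_system("random", 8, charges_e = 0.4, seed = s)
    hyd <- synth_hydrated_variant(core, 4, attach_stiffness = 0.2,
                                  shell_charge_e = 0.4, seed = s + 10)
    vib <- select_vibrational_modes(solve_modes(hyd))
    component_angles(mode_dipole(vib, "protein"),
                     mode_dipole(vib, "water"))$angles_deg
  })
  prof <- vapply(angs, function(a) mean(a[1:10], na.rm = TRUE), numeric(1))
  expect_true(all(prof > 90))
})

test_that("residue displacement profile matches hand arithmetic", {
  # eigenvector confined to residue 1 (atoms 1-2); residue 2 exactly 0
  ev <- c(1, 0, 0, 0, 1, 0, rep(0, 6))
  ms <- fix_handmade_modeset(ev)
  prof <- residue_displacement_profile(ms, 1)
  expect_identical(unname(prof["2"]), 0)
  expect_gt(prof["1"], 0)
  # uniform eigenvector over equal masses: identical residue values
  msu <- fix_handmade_modeset(rep(1, 12))
  profu <- residue_displacement_profile(msu, 1)
  expect_equal(unname(diff(profu)), 0)
  # hand-computed RMS on a known eigenvector
  ev2 <- c(3, 0, 0, 4, 0, 0, 1, 0, 0, 1, 1, 1)
  ms2 <- fix_handmade_modeset(ev2)
  scale <- sqrt(sum(rep(12 * K$amu, each = 1) * ev2^2 * 1))  # mass metric norm
  e <- ev2 / sqrt(sum(12 * K$amu * ev2^2))
  r1 <- sqrt(mean(c(sum(e[1:3]^2), sum(e[4:6]^2))))
  r2 <- sqrt(mean(c(sum(e[7:9]^2), sum(e[10:12]^2))))
  expect_equal(unname(residue_displacement_profile(ms2, 1)), c(r1, r2),
               tolerance = 1e-12)
  expect_error(residue_displacement_profile(ms2, 5), "out of range")
})
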