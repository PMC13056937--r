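test_that("susceptibility: empty sum, on-resonance values, split vs complex", {
  p <- lorentz_params(1e10, 3.011e23)
  empty <- fix_single_mode()
  empty$frequencies <- numeric(0)
  empty$magnitudes <- numeric(0)
  empty$vectors <- matrix(0, 3, 0)
  s0 <- susceptibility(empty, p, c(0, 1e11))
  expect_identical(s0$chi_real, c(0, 0))
  expect_identical(s0$chi_imag, c(0, 0))
  # single mode exactly on resonance: chi' = 0, chi'' = closed form
  dp <- fix_single_mode(nu_hz = 100e9, rho = 1e-21)
  s <- susceptibility(dp, p, 100e9)
  expect_identical(s$chi_real, 0)
  expect_equal(s$chi_imag,
               3.011e23 * 1e-42 / (12 * pi^2 * K$eps0 * 100e9 * 1e10),
               tolerance = 1e-12)
  # split and complex evaluation agree to machine precision
  grid <- seq(1e9, 500e9, by = 1e9)
  ss <- susceptibility(dp, p, grid)
  sc <- susceptibility_complex(dp, p, grid)
  expect_equal(ss$chi_real, Re(sc), tolerance = 1e-12)
  expect_equal(ss$chi_imag, Im(sc), tolerance = 1e-12)
  # guards
  expect_error(susceptibility(fix_single_mode(nu_hz = 0), p, grid),
               "rigid-body")
  expect_error(lorentz_params(0, 1), "gamma")
})

test_that("static limit, positivity and high-frequency decay", {
  sys <- build_harmonic_system("random", 8, seed = 2)
  vib <- select_vibrational_modes(solve_modes(sys))
  dp <- mode_dipole(vib)
  p <- lorentz_params(1e11, 3.011e23)
  s0 <- susceptibility(dp, p, 0)
  closed <- p$number_density / (12 * pi^2 * K$eps0) *
    sum(dp$magnitudes^2 / dp$frequencies^2)
  expect_equal(s0$chi_real, closed, tolerance = 1e-12)
  expect_identical(s0$chi_imag, 0)
  # chi'' > 0 for nu > 0 whenever some rho > 0
  grid <- seq(1e9, 2000e9, by = 5e9)
  s <- susceptibility(dp, p, grid)
  expect_true(all(s$chi_imag > 0))
  # |chi| <= C / nu^2 far above the highest mode
  numax <- max(dp$frequencies)
  far <- c(10, 20, 40) * numax
  sf <- susceptibility_complex(dp, p, far)
  bound <- p$number_density / (12 * pi^2 * K$eps0) * sum(dp$magnitudes^2)
  expect_true(all(Mod(sf) <= 1.1 * bound / (far^2 - numax^2)))
})

test_that("Kramers-Kronig reconstruction of chi-prime within 2 percent", {
  nu_l <- 100e9
  dp <- fix_single_mode(nu_hz = nu_l, rho = 1e-21)
  p <- lorentz_params(1e10, 3.011e23)
  grid <- seq(0.01 * nu_l, 100 * nu_l, by = 0.005 * nu_l)
  chi <- susceptibility(dp, p, grid)
  probes <- c(nu_l / 2, 2 * nu_l)
  rec <- kk_chi_real(grid, chi$chi_imag, probes)
  truth <- susceptibility(dp, p, probes)$chi_real
  expect_lt(max(abs(rec - truth) / abs(truth)), 0.02)
})

test_that("permittivity, extinction and absorption follow the closed relations", {
  expect_identical(extinction_coefficient(1, 0), 0)
  expect_equal(extinction_coefficient(3, 4), 1, tolerance = 1e-15)
  expect_equal(extinction_coefficient(0, 2), 1, tolerance = 1e-15)
  # alpha at nu = c/(4 pi) with k = 1 equals exactly 1 per metre
  dp <- fix_single_mode()
  p <- lorentz_params(1e10, 3.011e23, eps_infinity = 0)
  s <- dielectric_spectrum(dp, p, c(0, seq(1e9, 400e9, by = 1e9)))
  expect_identical(s$absorption[1], 0)            # alpha(0) = 0
  expect_true(all(s$absorption >= 0))
  expect_equal(s$eps_real, 1 + s$chi_real)
  expect_equal(s$eps_imag, s$chi_imag)
  expect_equal(s$absorption, 4 * pi * s$grid * s$extinction / K$c_light)
  # weak-loss approximation holds where eps'' << eps'
  weak <- abs(s$eps_imag) < 1e-3 * s$eps_real
  approx <- 2 * pi * s$grid / K$c_light * s$eps_imag / sqrt(s$eps_real)
  expect_equal(s$absorption[weak], approx[weak], tolerance = 1e-4)
  # eps_infinity enters eps' only
  p2 <- lorentz_params(1e10, 3.011e23, eps_infinity = 2)
  s2 <- dielectric_spectrum(dp, p2, s$grid)
  expect_equal(s2$eps_real, s$eps_real + 2)
  expect_equal(s2$eps_imag, s$eps_imag)
})

test_that("ensemble averaging is pointwise and matches brute force", {
  p <- lorentz_params(1e10, 3.011e23)
  grid <- seq(1e9, 300e9, by = 2e9)
  one <- dielectric_spectrum(fix_single_mode(90e9), p, grid)
  avg1 <- ensemble_average_spectra(list(one))
  expect_equal(avg1$absorption, one$absorption)
  expect_identical(max(avg1$sd$absorption), 0)
  avg2 <- ensemble_average_spectra(list(one, one))
  expect_equal(avg2$chi_imag, one$chi_imag)
  expect_lt(max(avg2$sd$chi_imag), 1e-30)
  # 10 jittered replicas vs brute-force mean at a probe frequency
  set.seed(3)
  nus <- 100e9 * (1 + stats::rnorm(10, sd = 0.05))
  sp <- lapply(nus, function(nu) dielectric_spectrum(fix_single_mode(nu), p, grid))
  avg <- ensemble_average_spectra(sp)
  probe <- which(grid == 101e9)
  brute <- mean(vapply(sp, function(s) s$absorption[probe], numeric(1)))
  expect_equal(avg$absorption[probe], brute, tolerance = 1e-14)
  bad <- dielectric_spectrum(fix_single_mode(), p, grid + 1e9)
  expect_error(ensemble_average_spectra(list(one, bad)), "identical frequency grid")
})

test_that("sweep: chi linear in concentration, gamma halving, dilute alpha", {
  sys <- build_harmonic_system("random", 8, seed = 2)
  dp <- mode_dipole(select_vibrational_modes(solve_modes(sys)))
  grid <- seq(1e9, 400e9, by = 2e9)
  sw <- sweep_spectra(dp, gammas_hz = 1e10,
                      concentrations_molar = c(0.5e-3, 1e-3), grid_hz = grid)
  s1 <- sw$spectrum[[1]]; s2 <- sw$spectrum[[2]]
  expect_equal(s2$chi_real, 2 * s1$chi_real, tolerance = 1e-12)
  expect_equal(s2$chi_imag, 2 * s1$chi_imag, tolerance = 1e-12)
  # dilute regime for alpha needs the concentration where chi' is small:
  # micromolar for these toy oscillator strengths
  swd <- sweep_spectra(dp, gammas_hz = 1e10,
                       concentrations_molar = c(1e-6, 2e-6), grid_hz = grid)
  s1 <- swd$spectrum[[1]]; s2 <- swd$spectrum[[2]]
  # doubling gamma halves single-mode on-resonance chi''
  one <- fix_single_mode(100e9)
  sa <- susceptibility(one, lorentz_params(1e10, 3.011e23), 100e9)
  sb <- susceptibility(one, lorentz_params(2e10, 3.011e23), 100e9)
  expect_equal(sa$chi_imag, 2 * sb$chi_imag, tolerance = 1e-12)
  # dilute limit: alpha(2c) deviates from 2*alpha(c) by < 1% when chi' small
  expect_lt(max(s1$chi_real), 0.01)
  dev <- abs(s2$absorption - 2 * s1$absorption) /
    pmax(2 * s1$absorption, .Machine$double.xmin)
  expect_lt(max(dev[s1$absorption > 0]), 0.01)
  expect_error(sweep_spectra(dp, 1e10, -1e-3), "negative")
  expect_error(sweep_spectra(dp, numeric(0), 1e-3), "nonempty")
})

test_that("stiff hydration shell blue-shifts the lowest absorption feature", {
  core <- build_harmonic_system("random", 10, seed = 1)
  hyd <- synth_hydrated_variant(core, 6, attach_stiffness = 2, seed = 2)
  p <- lorentz_params(5e9, 3.011e23)
  grid <- seq(1e9, 1000e9, by = 1e9)
  first_peak <- function(sys) {
    dp <- mode_dipole(select_vibrational_modes(solve_modes(sys)))
    a <- dielectric_spectrum(dp, p, grid)$absorption
    # first local maximum of the absorption curve
    i <- which(diff(sign(diff(a))) < 0)[1] + 1L
    grid[i]
  }
  expect_gte(first_peak(hyd), first_peak(core))
})
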