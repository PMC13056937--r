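#' Removed-water fraction from bound-water count and concentration
#'
#' Fraction of solvent water sequestered in hydration shells and lost to
#' the bulk sub-THz response: f_rm = n_b * c / c_water. With n_b = 1124
#' bound waters per protein and bulk-water molarity 55.345 mol/L this
#' gives the per-mM coefficient n_b / 55345 ~ 0.0203.
#'
#' @param n_b bound waters per protein molecule (>= 0).
#' @param conc_molar protein concentration, mol/L (>= 0).
#' @param water_molarity bulk-water molarity, mol/L; default 55.345
#'   (0.997 g/mL at 25 C, molar mass 18.015 g/mol).
#' @return dimensionless fraction f_rm in [0, 1].
#' @export
#' @examples
#' removed_water_fraction(1124, 0.517e-3) * 100  # percent
removed_water_fraction <- function(n_b, conc_molar,
                                   water_molarity = 55.345) {
  if (n_b < 0 || conc_molar < 0) stop("n_b and concentration must be >= 0")
  if (water_molarity <= 0) stop("water molarity must be > 0")
  f <- n_b * conc_molar / water_molarity
  if (any(f > 1))
    stop("f_rm > 1: unphysical concentration for this bound-water count")
  f
}

#' Dilute linear-mixing corrections for bound water
#'
#' In the dilute limit, sequestering a fraction f_rm of the water reduces
#' the solvent's contribution to the susceptibility in proportion:
#' delta-chi' = -f_rm * (eps'_w - 1), delta-chi'' = -f_rm * eps''_w.
#' The absorption delta follows by recomputing alpha from the adjusted
#' permittivity via the extinction relation. Water permittivity values
#' are caller-supplied (from a literature water model); none are
#' bundled.
#'
#' @param f_rm removed-water fraction, in [0, 1].
#' @param water_eps_real,water_eps_imag complex relative permittivity of
#'   bulk water at the probe frequency.
#' @param nu_hz probe frequency, Hz (needed for delta-alpha).
#' @return list with `delta_chi_real`, `delta_chi_imag` (dimensionless)
#'   and `delta_alpha` (m^-1, <= 0 for f_rm >= 0).
#' @export
#' @examples
#' dilute_mixing_deltas(0.0105, water_eps_real = 8.9,
#'                      water_eps_imag = 13.9, nu_hz = 100e9)
dilute_mixing_deltas <- function(f_rm, water_eps_real, water_eps_imag,
                                 nu_hz) {
  if (missing(water_eps_real) || missing(water_eps_imag))
    stop("water permittivity values must be supplied")
  if (f_rm < 0 || f_rm > 1) stop("f_rm must be in [0, 1]")
  d_re <- -f_rm * (water_eps_real - 1)
  d_im <- -f_rm * water_eps_imag
  a0 <- 4 * pi * nu_hz * extinction_coefficient(water_eps_real, water_eps_imag) /
    .const$c_light
  a1 <- 4 * pi * nu_hz *
    extinction_coefficient(water_eps_real + d_re, water_eps_imag + d_im) /
    .const$c_light
  list(delta_chi_real = d_re, delta_chi_imag = d_im,
       delta_alpha = a1 - a0)
}

#' Concentration conversions: molarity to mass concentration and number
#' density
#'
#' mass_conc (mg/mL) = c (mol/L) * molar_mass (g/mol); number density
#' N_V (m^-3) = c * 1000 * N_A.
#'
#' @param conc_molar concentration in mol/L (>= 0).
#' @param molar_mass_kg_mol molar mass in kg/mol (e.g. 38 for a ~38 kDa
#'   protein).
#' @return list with `mass_conc_mg_ml` and `number_density_m3`.
#' @export
#' @examples
#' concentration_conversions(0.5e-3, 38)  # 19 mg/mL, 3.011e23 m^-3
concentration_conversions <- function(conc_molar, molar_mass_kg_mol) {
  if (any(conc_molar < 0) || molar_mass_kg_mol < 0)
    stop("inputs must be >= 0")
  list(mass_conc_mg_ml = conc_molar * molar_mass_kg_mol * 1000,
       number_density_m3 = conc_molar * 1000 * .const$N_A)
}

#' Concentration at which hydration shells geometrically overlap
#'
#' Returns the mass concentration at which the per-molecule volume 1/N_V
#' equals the volume of a sphere of radius (protein effective radius +
#' shell thickness) -- simple sphere volumes, no packing-fraction
#' correction. Below this concentration inter-shell effects can be
#' neglected.
#'
#' @param protein_radius_nm effective protein radius, nm (> 0).
#' @param shell_thickness_angstrom hydration-shell thickness, Angstrom;
#'   default 3.
#' @param molar_mass_kg_mol protein molar mass, kg/mol.
#' @return overlap mass concentration in g/mL.
#' @export
shell_overlap_threshold <- function(protein_radius_nm,
                                    shell_thickness_angstrom = 3,
                                    molar_mass_kg_mol) {
  if (protein_radius_nm <= 0) stop("radius must be > 0")
  r_m <- protein_radius_nm * 1e-9 + shell_thickness_angstrom * 1e-10
  v <- 4 / 3 * pi * r_m^3                   # m^3 per molecule
  nv <- 1 / v                                # m^-3
  conc_molar <- nv / .const$N_A / 1000       # mol/L
  conc_molar * molar_mass_kg_mol             # kg/L == g/mL
}

#' Full bound-water mixing estimate
#'
#' Convenience wrapper combining [removed_water_fraction()],
#' [dilute_mixing_deltas()] and [concentration_conversions()].
#'
#' @param n_b bound waters per protein.
#' @param conc_molar protein concentration, mol/L.
#' @param water_eps_real,water_eps_imag bulk-water permittivity at
#'   `nu_hz` (caller-supplied).
#' @param nu_hz probe frequency, Hz.
#' @param molar_mass_kg_mol protein molar mass, kg/mol (for the mass
#'   concentration field); optional.
#' @param water_molarity bulk-water molarity, mol/L.
#' @return object of class `mixing_estimate` with all fields.
#' @export
mixing_estimate <- function(n_b, conc_molar, water_eps_real,
                            water_eps_imag, nu_hz,
                            molar_mass_kg_mol = NA_real_,
                            water_molarity = 55.345) {
  f <- removed_water_fraction(n_b, conc_molar, water_molarity)
  d <- dilute_mixing_deltas(f, water_eps_real, water_eps_imag, nu_hz)
  structure(list(
    n_b = n_b, conc_molar = conc_molar, f_rm = f,
    water_eps = c(real = water_eps_real, imag = water_eps_imag),
    nu_hz = nu_hz,
    delta_chi_real = d$delta_chi_real,
    delta_chi_imag = d$delta_chi_imag,
    delta_alpha = d$delta_alpha,
    mass_conc_mg_ml = if (is.na(molar_mass_kg_mol)) NA_real_
      else concentration_conversions(conc_molar, molar_mass_kg_mol)$mass_conc_mg_ml,
    water_molarity = water_molarity
  ), class = "mixing_estimate")
}

#' @export
print.mixing_estimate <- function(x, ...) {
  cat("<mixing_estimate> n_b = ", x$n_b, ", c = ",
      format(x$conc_molar * 1e3, digits = 4), " mM -> f_rm = ",
      format(100 * x$f_rm, digits = 4), "%\n",
      "  delta chi' = ", format(x$delta_chi_real, digits = 3),
      ", delta chi'' = ", format(x$delta_chi_imag, digits = 3),
      ", delta alpha = ", format(x$delta_alpha, digits = 3), " 1/m at ",
      format(x$nu_hz / 1e9), " GHz\n", sep = "")
  invisible(x)
}
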