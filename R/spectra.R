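#' Lorentz-oscillator model parameters
#'
#' @param gamma_hz phenomenological damping rate gamma in Hz (> 0),
#'   uniform across modes. Typical sweep: 10, 100, 1000, 10000 GHz.
#' @param number_density molecular number density N_V in m^-3 (>= 0).
#'   See [concentration_conversions()] to obtain it from molarity.
#' @param eps_infinity dimensionless high-frequency (electronic)
#'   permittivity offset added to eps_r'; default 0 (vibrational response
#'   only), option ~2 when an electronic background n^2 is wanted.
#' @param gamma_per_mode optional per-mode damping vector overriding
#'   `gamma_hz` (advanced; same length as the mode count at evaluation).
#' @return object of class `lorentz_params`. The isotropic orientation
#'   factor 1/3 is fixed, not a parameter.
#' @export
lorentz_params <- function(gamma_hz, number_density,
                           eps_infinity = 0, gamma_per_mode = NULL) {
  if (gamma_hz <= 0) stop("gamma must be > 0")
  if (number_density < 0) stop("number density must be >= 0")
  if (eps_infinity < 0) stop("eps_infinity must be >= 0")
  if (!is.null(gamma_per_mode) && any(gamma_per_mode <= 0))
    stop("per-mode gamma must be > 0")
  structure(list(gamma = gamma_hz, number_density = number_density,
                 eps_infinity = eps_infinity,
                 gamma_per_mode = gamma_per_mode,
                 orientation_factor = 1 / 3),
            class = "lorentz_params")
}

#' Complex susceptibility of a mode set on a frequency grid
#'
#' Sums damped Lorentz oscillators over modes:
#' chi(nu) = (N_V / (12 pi^2 eps0)) * sum_l rho_l^2 /
#'           (nu_l^2 - nu^2 - j nu gamma_l),
#' where the 1/(12 pi^2) combines the isotropic orientation factor 1/3
#' with 1/(4 pi^2) from the equation of motion in linear frequency.
#' Splitting with A_l = nu_l^2 - nu^2 and B_l = nu gamma_l gives
#' chi' with A_l and chi'' with B_l numerators over (A_l^2 + B_l^2).
#' Both routes are computed; they agree to machine precision and the
#' split form is returned.
#'
#' @param dipoles a `dipole_table` (all mode frequencies must be > 0:
#'   remove rigid-body modes first).
#' @param params a `lorentz_params`.
#' @param grid_hz numeric frequency grid, Hz, values >= 0.
#' @return object of class `dielectric_spectrum` with `grid`,
#'   `chi_real`, `chi_imag` filled; permittivity/extinction/absorption
#'   fields are completed by [permittivity_extinction_absorption()].
#' @export
susceptibility <- function(dipoles, params, grid_hz = default_grid_hz()) {
  stopifnot(inherits(dipoles, "dipole_table"), inherits(params, "lorentz_params"))
  if (any(grid_hz < 0)) stop("grid frequencies must be >= 0")
  nu_l <- dipoles$frequencies
  rho2 <- dipoles$magnitudes^2
  if (length(nu_l) && any(nu_l <= 0))
    stop("mode frequency <= 0: remove rigid-body modes before computing spectra")
  gam <- if (!is.null(params$gamma_per_mode)) {
    if (length(params$gamma_per_mode) != length(nu_l))
      stop("gamma_per_mode length must equal mode count")
    params$gamma_per_mode
  } else rep(params$gamma, length(nu_l))
  pref <- params$number_density / (12 * pi^2 * .const$eps0)
  if (length(nu_l) == 0L) {
    chi_re <- chi_im <- numeric(length(grid_hz))
  } else {
    # A = nu_l^2 - nu^2 (modes x grid), B = nu * gamma_l
    a <- outer(nu_l^2, grid_hz^2, `-`)
    b <- outer(gam, grid_hz)
    den <- a^2 + b^2
    chi_re <- pref * colSums(rho2 * a / den)
    chi_im <- pref * colSums(rho2 * b / den)
  }
  structure(list(grid = as.numeric(grid_hz),
                 chi_real = chi_re, chi_imag = chi_im,
                 eps_real = NULL, eps_imag = NULL,
                 extinction = NULL, absorption = NULL,
                 params = params),
            class = "dielectric_spectrum")
}

#' Default frequency grid: 1 to 2000 GHz in 1 GHz steps
#' @return numeric vector of frequencies in Hz.
#' @export
default_grid_hz <- function() seq(1e9, 2000e9, by = 1e9)

#' Complex susceptibility evaluated in complex arithmetic
#'
#' Direct evaluation of the complex Lorentz sum; the split real/imaginary
#' route in [susceptibility()] must agree with this to machine precision.
#' Exposed for validation.
#'
#' @inheritParams susceptibility
#' @return complex vector chi(nu) over the grid.
#' @export
susceptibility_complex <- function(dipoles, params, grid_hz = default_grid_hz()) {
  nu_l <- dipoles$frequencies
  rho2 <- dipoles$magnitudes^2
  gam <- if (!is.null(params$gamma_per_mode)) params$gamma_per_mode
         else rep(params$gamma, length(nu_l))
  pref <- params$number_density / (12 * pi^2 * .const$eps0)
  vapply(grid_hz, function(nu) {
    pref * sum(rho2 / complex(real = nu_l^2 - nu^2, imaginary = -nu * gam))
  }, complex(1))
}

#' Permittivity, extinction and absorption from susceptibility
#'
#' Completes a spectrum: eps_r' = 1 + eps_inf + chi', eps_r'' = chi'';
#' extinction from the complex refractive index n~^2 = eps_r,
#' k = sqrt( ( -eps_r' + sqrt(eps_r'^2 + eps_r''^2) ) / 2 ),
#' and absorption alpha = 4 pi nu k / c (m^-1). alpha at nu = 0 is 0 by
#' construction.
#'
#' @param chi a `dielectric_spectrum` from [susceptibility()], or a list
#'   with `grid`, `chi_real`, `chi_imag`.
#' @param params a `lorentz_params` (for the eps_infinity offset);
#'   defaults to the one stored in `chi`.
#' @return the completed `dielectric_spectrum`.
#' @export
permittivity_extinction_absorption <- function(chi, params = chi$params) {
  if (any(!is.finite(chi$chi_real)) || any(!is.finite(chi$chi_imag)))
    stop("susceptibility must be finite")
  eps_re <- 1 + params$eps_infinity + chi$chi_real
  eps_im <- chi$chi_imag
  k <- extinction_coefficient(eps_re, eps_im)
  alpha <- 4 * pi * chi$grid * k / .const$c_light
  out <- chi
  out$eps_real <- eps_re
  out$eps_imag <- eps_im
  out$extinction <- k
  out$absorption <- alpha
  out$params <- params
  class(out) <- "dielectric_spectrum"
  out
}

#' Extinction coefficient from real and imaginary relative permittivity
#'
#' k = sqrt( ( -eps' + sqrt(eps'^2 + eps''^2) ) / 2 ); defined for all
#' real eps', eps''.
#'
#' @param eps_real,eps_imag numeric vectors.
#' @return numeric vector k >= 0.
#' @export
extinction_coefficient <- function(eps_real, eps_imag) {
  sqrt(pmax(0, (-eps_real + sqrt(eps_real^2 + eps_imag^2)) / 2))
}

#' One-call spectrum: susceptibility then permittivity/absorption
#'
#' @inheritParams susceptibility
#' @return completed `dielectric_spectrum`.
#' @export
dielectric_spectrum <- function(dipoles, params, grid_hz = default_grid_hz()) {
  permittivity_extinction_absorption(susceptibility(dipoles, params, grid_hz))
}

#' @export
print.dielectric_spectrum <- function(x, ...) {
  cat("<dielectric_spectrum> ", length(x$grid), " points, ",
      format(min(x$grid) / 1e9), "-", format(max(x$grid) / 1e9), " GHz",
      if (!is.null(x$absorption)) paste0(", max alpha = ",
        format(max(x$absorption), digits = 4), " 1/m"),
      "\n", sep = "")
  invisible(x)
}

#' @export
as.data.frame.dielectric_spectrum <- function(x, ...) {
  data.frame(nu_Hz = x$grid,
             chi_re = x$chi_real, chi_im = x$chi_imag,
             eps_re = if (is.null(x$eps_real)) NA_real_ else x$eps_real,
             eps_im = if (is.null(x$eps_imag)) NA_real_ else x$eps_imag,
             k = if (is.null(x$extinction)) NA_real_ else x$extinction,
             alpha_per_m = if (is.null(x$absorption)) NA_real_ else x$absorption)
}

#' Pointwise mean and standard deviation over an ensemble of spectra
#'
#' Averages chi', chi'', eps', eps'', k and alpha independently per grid
#' point (so both chi-level and alpha-level means are available for
#' inspection). All spectra must share the same grid.
#'
#' @param spectra list of completed `dielectric_spectrum` objects.
#' @return `dielectric_spectrum` whose fields are the pointwise means,
#'   with an extra `sd` list of pointwise standard deviations.
#' @export
ensemble_average_spectra <- function(spectra) {
  if (!length(spectra)) stop("empty spectrum list")
  g <- spectra[[1]]$grid
  for (s in spectra)
    if (length(s$grid) != length(g) || any(s$grid != g))
      stop("all spectra must share an identical frequency grid")
  fields <- c("chi_real", "chi_imag", "eps_real", "eps_imag",
              "extinction", "absorption")
  out <- spectra[[1]]
  out$sd <- list()
  for (f in fields) {
    m <- vapply(spectra, function(s) {
      v <- s[[f]]
      if (is.null(v)) rep(NA_real_, length(g)) else v
    }, numeric(length(g)))
    m <- matrix(m, nrow = length(g))
    out[[f]] <- rowMeans(m)
    out$sd[[f]] <- if (ncol(m) > 1L) apply(m, 1, stats::sd) else rep(0, length(g))
  }
  out$n_replicas <- length(spectra)
  out
}

#' Damping x concentration sweep of spectra
#'
#' Computes one completed spectrum per (gamma, concentration)
#' combination. Number density is N_V = c * 1000 * N_A for c in mol/L.
#' Accepts either a single `dipole_table` or a list of them (one per
#' replica), in which case each cell holds the ensemble average.
#'
#' @param dipoles `dipole_table` or list thereof.
#' @param gammas_hz numeric vector of damping rates, Hz.
#' @param concentrations_molar numeric vector of concentrations, mol/L
#'   (>= 0).
#' @param grid_hz frequency grid, Hz.
#' @param eps_infinity permittivity offset, default 0.
#' @return data.frame with columns gamma_hz, concentration_molar and a
#'   list-column `spectrum` of `dielectric_spectrum` objects.
#' @export
sweep_spectra <- function(dipoles, gammas_hz, concentrations_molar,
                          grid_hz = default_grid_hz(), eps_infinity = 0) {
  if (!length(gammas_hz) || !length(concentrations_molar))
    stop("gamma and concentration lists must be nonempty")
  if (any(concentrations_molar < 0)) stop("negative concentration")
  if (inherits(dipoles, "dipole_table")) dipoles <- list(dipoles)
  combos <- expand.grid(gamma_hz = gammas_hz,
                        concentration_molar = concentrations_molar,
                        KEEP.OUT.ATTRS = FALSE)
  combos$spectrum <- lapply(seq_len(nrow(combos)), function(r) {
    nv <- combos$concentration_molar[r] * 1000 * .const$N_A
    p <- lorentz_params(combos$gamma_hz[r], nv, eps_infinity)
    sp <- lapply(dipoles, dielectric_spectrum, params = p, grid_hz = grid_hz)
    if (length(sp) == 1L) sp[[1]] else ensemble_average_spectra(sp)
  })
  combos
}

#' Kramers-Kronig reconstruction of chi' from chi''
#'
#' Numerical principal-value evaluation of
#' chi'(nu) = (2/pi) P int_0^inf nu' chi''(nu') / (nu'^2 - nu^2) d nu'
#' by trapezoid quadrature with the singular grid point excluded.
#' A causal (Lorentz) spectrum sampled on a grid spanning well past its
#' resonances reconstructs chi' to a few percent; used to validate the
#' spectral numerics, not as a production path.
#'
#' @param grid_hz dense increasing frequency grid on which `chi_imag`
#'   is sampled.
#' @param chi_imag chi'' sampled on `grid_hz`.
#' @param nu_eval_hz frequencies at which to reconstruct chi'.
#' @return numeric vector of reconstructed chi' values.
#' @export
kk_chi_real <- function(grid_hz, chi_imag, nu_eval_hz) {
  stopifnot(length(grid_hz) == length(chi_imag))
  vapply(nu_eval_hz, function(nu) {
    integrand <- grid_hz * chi_imag / (grid_hz^2 - nu^2)
    # drop points too close to the pole; trapezoid over the rest
    ok <- abs(grid_hz - nu) > .Machine$double.eps^0.5 * nu
    x <- grid_hz[ok]; y <- integrand[ok]
    # symmetric exclusion: principal value cancels the pole's two sides
    (2 / pi) * sum(diff(x) * (y[-1] + y[-length(y)]) / 2)
  }, numeric(1))
}
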