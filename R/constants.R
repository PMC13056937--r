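#' Physical constants used throughout the package
#'
#' CODATA-2018 values, SI units. All internal computation is SI: masses in
#' kg, charges in C, frequencies in Hz (linear frequency, not angular),
#' lengths in m unless an interface says otherwise.
#'
#' @return Named list with elements:
#'   \describe{
#'     \item{c_light}{speed of light in vacuum, m/s}
#'     \item{eps0}{vacuum permittivity, F/m}
#'     \item{N_A}{Avogadro constant, 1/mol}
#'     \item{e_charge}{elementary charge, C}
#'     \item{amu}{atomic mass unit, kg}
#'     \item{cm1_to_hz}{wavenumber-to-frequency factor, Hz per cm^-1}
#'   }
#' @export
#' @examples
#' physical_constants()$c_light
physical_constants <- function() {
  list(
    c_light   = 299792458,
    eps0      = 8.8541878128e-12,
    N_A       = 6.02214076e23,
    e_charge  = 1.602176634e-19,
    amu       = 1.66053906660e-27,
    cm1_to_hz = 2.99792458e10
  )
}

.const <- list(
  c_light   = 299792458,
  eps0      = 8.8541878128e-12,
  N_A       = 6.02214076e23,
  e_charge  = 1.602176634e-19,
  amu       = 1.66053906660e-27,
  cm1_to_hz = 2.99792458e10
)
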