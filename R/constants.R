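#' Physical constants (CODATA 2018)
#'
#' Frozen table of the physical constants used throughout the package, in SI
#' units. Kept in one place so every derived quantity (wavelength, dose,
#' detector current) traces to the same values.
#'
#' @format A named list:
#' \describe{
#'   \item{h}{Planck constant, J s}
#'   \item{m0}{electron rest mass, kg}
#'   \item{e}{elementary charge, C}
#'   \item{c}{speed of light in vacuum, m/s}
#' }
#' @export
codata <- list(
  h  = 6.62607015e-34,
  m0 = 9.1093837015e-31,
  e  = 1.602176634e-19,
  c  = 299792458
)

# Gold FCC lattice parameter, Angstrom. Used by the powder reference profile.
AU_LATTICE_A <- 4.0782
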