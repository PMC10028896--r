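## Unit system used throughout: length nm, energy kcal/mol, temperature K,
## charge e, mass amu, time ps. One internal conversion factor turns
## kcal/mol into the MD-consistent kJ/mol (amu nm^2/ps^2) for dynamics.

#' Physical constants for the toy unit system
#'
#' Boltzmann constant in kcal/mol/K, the Coulomb constant in
#' kcal·nm/(mol·e²), and the kcal-to-kJ conversion used by the integrator.
#'
#' @format Named list with elements `kB` (kcal/mol/K), `coulomb`
#'   (kcal·nm/(mol·e²)) and `kcal_to_kj` (dimensionless).
#' @export
#' @examples
#' alchrex_constants$kB * 300  # kT at 300 K, kcal/mol
alchrex_constants <- list(
  kB = 0.0019872041,
  coulomb = 33.20637,
  kcal_to_kj = 4.184
)

#' Thermal energy kT
#'
#' @param temperature Temperature in K.
#' @return kT in kcal/mol.
#' @export
#' @examples
#' kt_kcal(300)
kt_kcal <- function(temperature) {
  stopifnot(is.numeric(temperature), temperature > 0)
  alchrex_constants$kB * temperature
}
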