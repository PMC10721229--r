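#' Physical constants used throughout the package
#'
#' CODATA 2018 exact values, pinned in one place so every unit chain in the
#' package (Debye lengths, Boltzmann factors, virial integrals) draws on the
#' same numbers.
#'
#' @format A named list:
#' \describe{
#'   \item{e}{elementary charge, C}
#'   \item{k_B}{Boltzmann constant, J/K}
#'   \item{N_A}{Avogadro constant, 1/mol}
#'   \item{eps_0}{vacuum permittivity, F/m}
#'   \item{R_kJ}{molar gas constant, kJ/mol/K}
#' }
#' @export
#' @examples
#' phys_constants$R_kJ * 300  # RT at 300 K, kJ/mol
phys_constants <- list(
  e     = 1.602176634e-19,
  k_B   = 1.380649e-23,
  N_A   = 6.02214076e23,
  eps_0 = 8.8541878128e-12,
  R_kJ  = 1.380649e-23 * 6.02214076e23 / 1000
)

#' Thermal energy RT in kJ/mol
#'
#' @param temperature temperature in K
#' @return RT in kJ/mol
#' @export
#' @examples
#' rt_kj(300)  # about 2.494 kJ/mol
rt_kj <- function(temperature) {
  stopifnot(is.numeric(temperature), temperature > 0)
  phys_constants$R_kJ * temperature
}
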