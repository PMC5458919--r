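# Physical constants and unit conversions. All resistances are SI
# (Pa s m^-3); geometry is carried in Angstrom, slip lengths in nm, and
# converted here, never inline.

#' Physical constants used throughout
#'
#' @format Named list: `R_gas` (J mol^-1 K^-1), `N_A` (mol^-1),
#'   `Pa_per_katm` (Pa per kiloatmosphere), `m_per_A` (metres per Angstrom),
#'   `m_per_nm` (metres per nanometre).
#' @export
ph_constants <- list(
  R_gas = 8.314462618,
  N_A = 6.02214076e23,
  Pa_per_katm = 1.01325e8,
  m_per_A = 1e-10,
  m_per_nm = 1e-9
)

#' Convert Angstrom to metres
#' @param x length in Angstrom
#' @return length in metres
#' @export
A_to_m <- function(x) x * ph_constants$m_per_A

#' Convert nanometres to metres
#' @param x length in nm
#' @return length in metres
#' @export
nm_to_m <- function(x) x * ph_constants$m_per_nm

#' Convert kiloatmospheres to Pascal
#' @param x pressure in katm
#' @return pressure in Pa
#' @export
katm_to_Pa <- function(x) x * ph_constants$Pa_per_katm

#' Molecular volume of water
#'
#' @param V_w_cm3_mol molar volume in cm^3/mol (default 18)
#' @return volume of one molecule in m^3
#' @export
water_molecular_volume <- function(V_w_cm3_mol = 18) {
  (V_w_cm3_mol * 1e-6) / ph_constants$N_A
}
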