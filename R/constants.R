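## Physical constants and unit conversions.
##
## Internal unit system: lengths in angstrom (A), energies in zeptojoule
## (zJ = 1e-21 J), pressures in pascal (Pa), temperatures in kelvin.
## Pressures enter energies only through the combination P * volume, where
## volumes are in A^3; 1 Pa * A^3 = 1e-30 J = 1e-9 zJ.

#' Physical constants used throughout the package
#'
#' All energies are handled in zeptojoule (zJ, 1e-21 J), lengths in angstrom
#' and pressures in pascal. `pa_a3_to_zj` converts a pressure-volume product
#' in Pa * A^3 to zJ; `kB_zJ` is the Boltzmann constant in zJ/K.
#'
#' @format A named list with elements `kB_zJ`, `pa_a3_to_zj`.
#' @export
lamstack_constants <- list(
  kB_zJ = 1.380649e-2,      # Boltzmann constant, zJ / K
  pa_a3_to_zj = 1e-9        # 1 Pa * 1 A^3 in zJ
)

#' Thermal energy in zJ
#'
#' @param T_K temperature in kelvin.
#' @return k_B T in zJ.
#' @export
kBT_zJ <- function(T_K) lamstack_constants$kB_zJ * T_K
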