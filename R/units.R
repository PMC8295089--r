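#' Physical constants and the internal unit system
#'
#' All internal arithmetic uses Angstrom (length), amu (mass),
#' kcal mol^-1 (energy) and Kelvin (temperature). Frequencies are reported
#' in s^-1, entropies in J K^-1 mol^-1 with a kcal mol^-1 K^-1 view where
#' useful.
#'
#' The bridge between the internal unit system and SI is exact because
#' amu * Avogadro = 1 g: an acceleration-like quantity in
#' kcal mol^-1 / (Angstrom^2 amu) converts to s^-2 by the single factor
#' 4.184e26.
#'
#' @name eemcc-units
#' @keywords internal
NULL

## Boltzmann constant, kcal mol^-1 K^-1
KB_KCAL <- 0.0019872041

## Gas constant, J K^-1 mol^-1 (kB expressed per mole in SI)
R_J <- 8.314

## kcal -> J
KCAL_TO_J <- 4184

## Planck constant expressed per mole in the internal energy unit:
## 6.62607015e-34 J s  *  6.02214076e23 mol^-1  /  4184 J kcal^-1
H_KCAL_S <- 6.62607015e-34 * 6.02214076e23 / 4184

## (kcal mol^-1 Angstrom^-2 amu^-1) -> s^-2.
## 4184 J/kcal / (NA * 1 amu[kg] * 1e-20 m^2/A^2); NA * amu = 1e-3 kg exactly.
FREQ2_SI <- 4184 / (1e-3 * 1e-20)

#' Convert an entropy from kcal mol^-1 K^-1 to J K^-1 mol^-1
#' @param s_kcal entropy in kcal mol^-1 K^-1
#' @return entropy in J K^-1 mol^-1
#' @export
entropy_to_joules <- function(s_kcal) s_kcal * KCAL_TO_J

#' Convert an entropy from J K^-1 mol^-1 to kcal mol^-1 K^-1
#' @param s_j entropy in J K^-1 mol^-1
#' @return entropy in kcal mol^-1 K^-1
#' @export
entropy_to_kcal <- function(s_j) s_j / KCAL_TO_J
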