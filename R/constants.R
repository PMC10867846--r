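#' Physical constants and unit conversions
#'
#' Internal units are atomic units throughout: bohr for length, elementary
#' charge for charge, hartree/e for potential, bohr^3 for polarizability.
#' Angstrom and Debye appear only at I/O boundaries.
#'
#' @name dpolkit-units
#' @keywords internal
NULL

## CODATA conversion factors
BOHR_PER_ANGSTROM <- 1.8897261254578281
ANGSTROM_PER_BOHR <- 1 / BOHR_PER_ANGSTROM
DEBYE_PER_AU <- 2.541746473          # 1 au dipole (e*bohr) in Debye
KBOLTZ_HARTREE <- 3.166811563e-6     # Boltzmann constant, hartree / K
AVOGADRO <- 6.02214076e23
BOHR_IN_CM <- 0.529177210903e-8
BOHR3_IN_ML <- BOHR_IN_CM^3          # bohr^3 in cm^3 (= mL)
NM3_IN_BOHR3 <- (10 * BOHR_PER_ANGSTROM)^3

#' Bondi van der Waals radii
#'
#' Default radius set (Angstrom) used for Merz-Singh-Kollman shell
#' construction. Covers the trained CHON scope plus a few common elements.
#'
#' @return Named numeric vector of radii in Angstrom.
#' @export
#' @examples
#' bondiRadii()[["C"]]
bondiRadii <- function() {
  c(H = 1.20, C = 1.70, N = 1.55, O = 1.52,
    F = 1.47, P = 1.80, S = 1.80, Cl = 1.75, Br = 1.85)
}
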