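#' Physical constants
#'
#' CODATA values of the physical constants used throughout the package,
#' pinned in one place so that every affinity, entropy production and
#' photon-energy calculation uses identical numbers.
#'
#' @return A named list with elements `h` (Planck constant, J s), `c`
#'   (speed of light, m/s), `k_B` (Boltzmann constant, J/K), `N_A`
#'   (Avogadro constant, 1/mol) and `R` (molar gas constant, J/(mol K)).
#' @examples
#' physical_constants()$R
#' @export
physical_constants <- function() {
  list(
    h   = 6.62607015e-34,
    c   = 299792458.0,
    k_B = 1.380649e-23,
    N_A = 6.02214076e23,
    R   = 8.31446261815
  )
}

# molar gas constant, used internally everywhere affinities are molar
.R_GAS <- 8.31446261815

#' Default temperature for kinetic schemes, kelvin (room temperature).
#' @keywords internal
.DEFAULT_T <- 298.16
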