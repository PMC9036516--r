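#' Physical constants and unit conversions
#'
#' Single source of truth for every unit conversion in the package.
#' Internal unit system: lengths in Angstrom, energies in kJ/mol, charges in
#' elementary charge units, temperature in Kelvin.  The quantum-chemistry
#' boundary works in Hartree atomic units; conversion happens only through
#' this table.
#'
#' @return Named list with elements
#'   \describe{
#'     \item{k_B}{Boltzmann constant as molar gas constant, kJ/(mol K).}
#'     \item{coulomb}{Coulomb constant \eqn{e^2/(4\pi\epsilon_0)} in
#'       kJ Angstrom / (mol e^2).}
#'     \item{hartree_kjmol}{1 Hartree in kJ/mol.}
#'     \item{bohr_angstrom}{1 Bohr in Angstrom.}
#'     \item{avogadro}{Avogadro constant, 1/mol.}
#'   }
#' @examples
#' rism_constants()$k_B * 298.15   # thermal energy at room temperature
#' @export
rism_constants <- function() {
  list(
    k_B           = 0.008314462618153242,  # kJ/(mol K), CODATA 2018 R
    coulomb       = 1389.3545764438197,    # kJ A/(mol e^2)
    hartree_kjmol = 2625.4996394798254,
    bohr_angstrom = 0.529177210903,
    avogadro      = 6.02214076e23
  )
}

# internal shortcut (avoids rebuilding the list in hot loops)
.k <- rism_constants()

#' Thermodynamic state
#'
#' @param temperature Absolute temperature in K (default 298.15).
#' @return An object of class `thermo_state` with fields `temperature` (K)
#'   and `beta` = 1/(k_B T) in mol/kJ.
#' @examples
#' th <- thermo_state(298.15)
#' th$beta
#' @export
thermo_state <- function(temperature = 298.15) {
  if (!is.numeric(temperature) || length(temperature) != 1L || temperature <= 0)
    stop("temperature must be a single positive number (K)")
  structure(
    list(temperature = temperature, beta = 1 / (.k$k_B * temperature)),
    class = "thermo_state"
  )
}

#' @export
print.thermo_state <- function(x, ...) {
  cat(sprintf("<thermo_state> T = %.4g K, beta = %.8g mol/kJ\n",
              x$temperature, x$beta))
  invisible(x)
}
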