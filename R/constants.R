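# Physical constants (CODATA 2018) and internal unit conventions.
#
# Internal units are fixed throughout the package:
#   length  Angstrom, energy kJ/mol, temperature K, mass amu (g/mol).
# Entropies are reported in J K^-1 mol^-1, enthalpies and free energies in
# kJ mol^-1, matching the conventional table units of the field.

#' Physical constants used by eemcc
#'
#' A named list of the physical constants the entropy machinery needs, in SI
#' units except where noted: `kB` (J/K), `h` (J s), `NA` (1/mol), `R`
#' (J/K/mol), `amu` (kg), `kcal` (kJ per kcal, 4.184).
#'
#' @format Named list of numbers.
#' @export
mcc_constants <- list(
  kB   = 1.380649e-23,       # Boltzmann, J/K
  h    = 6.62607015e-34,     # Planck, J s
  NA_  = 6.02214076e23,      # Avogadro, 1/mol
  R    = 8.31446261815324,   # gas constant, J/K/mol
  amu  = 1.66053906660e-27,  # atomic mass unit, kg
  kcal = 4.184               # kJ per kcal
)

# kB*T in internal energy units (kJ/mol)
.kBT_kJ <- function(temperature) mcc_constants$R * temperature / 1000

# Covariance eigenvalues are accumulated in (kJ mol^-1 A^-1)^2 / amu for
# forces and the numerically identical (kJ mol^-1)^2 / (amu A^2) for torques.
# One factor converts either to SI (per molecule) for the frequency formula.
.FORCE_SI <- 1e3 / (mcc_constants$NA_ * 1e-10)  # (kJ/mol/A) -> J/m, per molecule
.LAMBDA_SI <- .FORCE_SI^2 / mcc_constants$amu   # eigenvalue unit -> SI
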