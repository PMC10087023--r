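# Enthalpy partition and free-energy assembly.
#
# The ensemble-average system Hamiltonian is split into per-atom terms
# <K_i> + <U_i> (engine-dumped kinetic and potential energies, with shared
# interaction terms already divided equally among participating atoms), and
# any grouping of atoms sums its members: H_j = sum_{i in j} (<K_i> + <U_i>).
# The PV term (order of J/mol per molecule at ambient pressure) is neglected
# by default but can be added back for sensitivity checks.

#' Partition the mean system enthalpy over a grouping of atoms
#'
#' @param frames An `mcc_frames` object with per-atom energies.
#' @param grouping Either a factor/vector of group labels, one per atom, or
#'   one of `"ua"`, `"monomer"`, `"polymer"` (resolved via `hierarchy`).
#' @param hierarchy Required when `grouping` is a level name.
#' @param pv Optional PV term in kJ/mol for the whole system, divided
#'   equally over atoms (default 0, i.e. neglected).
#' @return An object of class `mcc_energy_ledger`: data.frame (`group`,
#'   `n_atoms`, `K`, `U`, `H` in kJ/mol) with the system total as attribute
#'   `H_total`.
#' @export
unit_enthalpy <- function(frames, grouping, hierarchy = NULL, pv = 0) {
  if (is.null(frames$pe) || is.null(frames$ke))
    stop("FrameBatch has no per-atom energies; supply an energy stream ",
         "(LAMMPS pe/atom+ke/atom dump converted to the TSV dialect: ",
         "columns frame, atom, pe, ke)")
  if (is.character(grouping) && length(grouping) == 1) {
    if (is.null(hierarchy)) stop("level grouping needs a hierarchy")
    grouping <- hierarchy$atoms[[if (grouping == "ua") "ua" else grouping]]
  }
  stopifnot(length(grouping) == frames$n_atoms)
  k_mean <- colMeans(frames$ke) + pv / frames$n_atoms
  u_mean <- colMeans(frames$pe)
  g <- factor(grouping)
  led <- data.frame(
    group = levels(g),
    n_atoms = as.integer(table(g)),
    K = as.numeric(tapply(k_mean, g, sum)),
    U = as.numeric(tapply(u_mean, g, sum)),
    stringsAsFactors = FALSE
  )
  led$H <- led$K + led$U
  structure(led, H_total = sum(k_mean) + sum(u_mean),
            class = c("mcc_energy_ledger", "data.frame"))
}

#' Assemble free energy G = H - TS
#'
#' @param H Enthalpies in kJ/mol.
#' @param S Entropies in J/K/mol (converted internally).
#' @param temperature Temperature in K.
#' @return data.frame with `H` (kJ/mol), `TS` (kJ/mol), `G = H - TS`
#'   (kJ/mol).
#' @export
free_energy <- function(H, S, temperature) {
  stopifnot(length(H) == length(S))
  TS <- temperature * S / 1000
  data.frame(H = H, TS = TS, G = H - TS)
}

#' Build a thermodynamic summary table
#'
#' Combines per-group enthalpy and entropy into the standard report layout.
#'
#' @param groups Group labels.
#' @param H Enthalpy per group, kJ/mol.
#' @param S Entropy per group, J/K/mol.
#' @param n Count per group (e.g. waters in the group).
#' @param temperature Temperature in K.
#' @return data.frame (`group`, `H`, `S`, `TS`, `G`, `N`).
#' @export
thermo_table <- function(groups, H, S, n, temperature) {
  fe <- free_energy(H, S, temperature)
  data.frame(group = groups, H = fe$H, S = S, TS = fe$TS, G = fe$G, N = n,
             stringsAsFactors = FALSE)
}
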