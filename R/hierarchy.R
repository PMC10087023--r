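# The three-level unit hierarchy of multiscale cell correlation:
# united atoms (a heavy atom plus its bonded hydrogens), monomers (protein
# residues, water molecules, ions) and polymers (whole molecules).

WATER_RESNAMES <- c("HOH", "WAT", "TIP3", "TIP3P", "TIP4", "SPC", "SPCE",
                    "SOL", "H2O")
ION_ELEMENTS <- c("NA", "CL", "K", "MG", "CA", "ZN", "LI", "BR", "I", "F",
                  "RB", "CS")
BACKBONE_NAMES <- c(N = "N", CA = "CA", C = "C")

#' Build the united-atom / monomer / polymer hierarchy from a topology
#'
#' Groups every heavy atom with its bonded hydrogens into a united atom (UA),
#' assigns each atom to exactly one monomer (protein residue, water molecule
#' or ion) and polymer (whole molecule), and classifies every UA's rotational
#' geometry: `nonlinear` (two or more hydrogens, 3 rotational modes),
#' `linear` (exactly one hydrogen, 2 modes) or `point` (no hydrogens,
#' 0 modes). Classification uses the topology's hydrogen count only, not
#' instantaneous geometry, so it is deterministic.
#'
#' @param topology A topology list from [read_topology_tsv()] or [read_psf()].
#' @return An object of class `mcc_hierarchy`: a list with `atoms` (the atom
#'   table extended with `is_hydrogen`, `ua`, `monomer`, `polymer` columns),
#'   `ua` (one row per united atom: heavy atom, geometry class, hydrogen
#'   count, parent ids), `ua_hydrogens` (list of hydrogen indices per UA),
#'   `monomers` (id, kind, residue name and backbone atom indices), and
#'   `polymers` (id, net charge, monomer count).
#' @export
build_hierarchy <- function(topology) {
  atoms <- topology$atoms
  n <- nrow(atoms)
  adj <- bond_adjacency(n, topology$bonds)
  is_h <- atoms$element == "H"

  # UA assignment: every hydrogen joins the heavy atom it is bonded to
  ua_of <- integer(n)
  heavy_idx <- which(!is_h)
  ua_of[heavy_idx] <- seq_along(heavy_idx)
  for (i in which(is_h)) {
    nb <- adj[[i]]
    heavy_nb <- nb[!is_h[nb]]
    if (length(heavy_nb) == 0)
      stop("hydrogen atom ", i, " (", atoms$name[i],
           ") is not bonded to any heavy atom")
    ua_of[i] <- ua_of[heavy_nb[1]]
  }

  ua_hydrogens <- split(which(is_h), ua_of[is_h])
  n_ua <- length(heavy_idx)
  hyd_list <- vector("list", n_ua)
  hyd_list[as.integer(names(ua_hydrogens))] <- ua_hydrogens
  n_h <- lengths(hyd_list)
  geometry <- c("point", "linear", "nonlinear")[pmin(n_h, 2L) + 1L]

  # Monomers: one per (molid, resid); polymers: one per molid
  mon_key <- paste(atoms$molid, atoms$resid, sep = "_")
  mon_of <- match(mon_key, unique(mon_key))
  pol_of <- match(atoms$molid, unique(atoms$molid))

  first_atom <- match(unique(mon_key), mon_key)
  mon_resname <- toupper(atoms$resname[first_atom])
  mon_size <- tabulate(mon_of)
  kind <- ifelse(mon_resname %in% WATER_RESNAMES, "water",
          ifelse(mon_size == 1 & atoms$element[first_atom] %in% ION_ELEMENTS,
                 "ion", "protein_residue"))
  bad_water <- which(kind == "water" & mon_size != 3)
  if (length(bad_water) > 0)
    stop("water monomer(s) without exactly 3 atoms: ",
         paste(bad_water, collapse = ", "))

  n_mon <- length(first_atom)
  backbone <- matrix(NA_integer_, n_mon, 3,
                     dimnames = list(NULL, c("N", "CA", "C")))
  for (bb in c("N", "CA", "C")) {
    hits <- which(atoms$name == bb)
    backbone[mon_of[hits], bb] <- hits
  }
  backbone[kind != "protein_residue", ] <- NA_integer_

  atoms$is_hydrogen <- is_h
  atoms$ua <- ua_of
  atoms$monomer <- mon_of
  atoms$polymer <- pol_of

  ua <- data.frame(
    id = seq_len(n_ua),
    heavy = heavy_idx,
    n_h = n_h,
    geometry = geometry,
    monomer = mon_of[heavy_idx],
    polymer = pol_of[heavy_idx],
    stringsAsFactors = FALSE
  )

  monomers <- data.frame(
    id = seq_len(n_mon),
    kind = kind,
    resname = mon_resname,
    resid = atoms$resid[first_atom],
    polymer = pol_of[first_atom],
    n_atoms = mon_size,
    stringsAsFactors = FALSE
  )
  monomers <- cbind(monomers, as.data.frame(backbone))

  pol_ids <- seq_along(unique(atoms$molid))
  polymers <- data.frame(
    id = pol_ids,
    net_charge = as.numeric(tapply(atoms$charge, pol_of, sum)),
    n_monomers = as.integer(table(factor(monomers$polymer, levels = pol_ids))),
    n_atoms = as.integer(table(factor(pol_of, levels = pol_ids))),
    stringsAsFactors = FALSE
  )

  structure(list(atoms = atoms, ua = ua, ua_hydrogens = hyd_list,
                 monomers = monomers, polymers = polymers,
                 bonds = topology$bonds, adjacency = adj),
            class = "mcc_hierarchy")
}

#' @export
print.mcc_hierarchy <- function(x, ...) {
  cat("mcc_hierarchy:", nrow(x$atoms), "atoms,", nrow(x$ua), "united atoms,",
      nrow(x$monomers), "monomers,", nrow(x$polymers), "polymers\n")
  cat("  monomer kinds:",
      paste(names(table(x$monomers$kind)), table(x$monomers$kind),
            collapse = ", "), "\n")
  invisible(x)
}

# Atom indices belonging to each unit of a level
unit_atoms <- function(hierarchy, level = c("ua", "monomer", "polymer")) {
  level <- match.arg(level)
  key <- hierarchy$atoms[[if (level == "ua") "ua" else level]]
  split(seq_len(nrow(hierarchy$atoms)), key)
}

# Rotational mode count by geometry class: nonlinear 3, linear 2, point 0
rot_modes <- function(geometry) {
  c(nonlinear = 3L, linear = 2L, point = 0L)[geometry]
}
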