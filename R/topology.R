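# Topology ingestion: a minimal two-file TSV dialect (atoms + bonds) used by
# the synthetic fixtures, and a PSF reader for engine-generated systems.
#
# A parsed topology is a list with
#   atoms: data.frame(index, name, element, resid, resname, molid, mass, charge)
#   bonds: integer matrix, two columns of 1-based atom indices
# Atom indices are 1-based and contiguous.

#' Read a topology from the package's TSV dialect
#'
#' The atoms file is tab-separated with columns `index`, `name`, `element`,
#' `resid`, `resname`, `molid`, `mass` (amu) and `charge` (e). The bonds file
#' has two columns `i`, `j` of 1-based atom indices. This dialect exists so
#' that fixtures and toy systems need no MD engine.
#'
#' @param atoms_path Path to the atoms TSV.
#' @param bonds_path Path to the bonds TSV.
#' @return A topology list with elements `atoms` and `bonds`.
#' @export
read_topology_tsv <- function(atoms_path, bonds_path) {
  atoms <- read_tsv_file(atoms_path)
  need <- c("index", "name", "element", "resid", "resname", "molid",
            "mass", "charge")
  miss <- setdiff(need, names(atoms))
  if (length(miss) > 0)
    stop("atoms file missing columns: ", paste(miss, collapse = ", "))
  bonds <- as.matrix(read_tsv_file(bonds_path)[, c("i", "j")])
  storage.mode(bonds) <- "integer"
  validate_topology(list(atoms = atoms, bonds = bonds))
}

#' Read a CHARMM/X-PLOR PSF topology
#'
#' Parses the `!NATOM` and `!NBOND` sections of a PSF file, which carry the
#' masses, partial charges and bond list the hierarchy needs. Element symbols
#' are inferred from atom masses.
#'
#' @param path Path to a PSF file.
#' @return A topology list with elements `atoms` and `bonds`.
#' @export
read_psf <- function(path) {
  lines <- readLines(path)
  natom_at <- grep("!NATOM", lines)
  nbond_at <- grep("!NBOND", lines)
  if (length(natom_at) != 1)
    stop("not a PSF file (no !NATOM section): ", path)
  n_atoms <- as.integer(strsplit(trimws(lines[natom_at]), "\\s+")[[1]][1])
  atom_lines <- lines[(natom_at + 1):(natom_at + n_atoms)]
  tok <- strsplit(trimws(atom_lines), "\\s+")
  atoms <- data.frame(
    index   = seq_len(n_atoms),
    name    = vapply(tok, `[`, "", 5),
    resid   = as.integer(vapply(tok, `[`, "", 3)),
    resname = vapply(tok, `[`, "", 4),
    segname = vapply(tok, `[`, "", 2),
    charge  = as.numeric(vapply(tok, `[`, "", 7)),
    mass    = as.numeric(vapply(tok, `[`, "", 8)),
    stringsAsFactors = FALSE
  )
  atoms$element <- element_from_mass(atoms$mass)
  # molid: contiguous runs of the same segment name
  atoms$molid <- cumsum(c(TRUE, atoms$segname[-1] != atoms$segname[-n_atoms]))
  atoms$segname <- NULL
  bonds <- integer(0)
  if (length(nbond_at) == 1) {
    n_bonds <- as.integer(strsplit(trimws(lines[nbond_at]), "\\s+")[[1]][1])
    i <- nbond_at + 1
    vals <- integer(0)
    while (length(vals) < 2 * n_bonds && i <= length(lines)) {
      vals <- c(vals, as.integer(strsplit(trimws(lines[i]), "\\s+")[[1]]))
      i <- i + 1
    }
    bonds <- matrix(vals[seq_len(2 * n_bonds)], ncol = 2, byrow = TRUE)
  }
  bonds <- matrix(as.integer(bonds), ncol = 2)
  colnames(bonds) <- c("i", "j")
  validate_topology(list(atoms = atoms, bonds = bonds))
}

validate_topology <- function(topo) {
  atoms <- topo$atoms
  if (any(!is.finite(atoms$mass)) || any(atoms$mass <= 0))
    stop("topology has missing or non-positive atom masses")
  if (!identical(atoms$index, seq_len(nrow(atoms))))
    stop("atom indices must be contiguous and 1-based")
  if (length(topo$bonds) > 0 &&
      (max(topo$bonds) > nrow(atoms) || min(topo$bonds) < 1))
    stop("bond list references atoms outside the topology")
  topo$atoms$element <- toupper(topo$atoms$element)
  topo
}

# Mass -> element for the atoms common in biomolecular force fields.
element_from_mass <- function(mass) {
  ref <- c(H = 1.008, C = 12.011, N = 14.007, O = 15.999, S = 32.06,
           P = 30.974, NA2 = 22.990, CL = 35.45, K = 39.098, MG = 24.305,
           CA2 = 40.078, ZN = 65.38, F = 18.998)
  nm <- c("H", "C", "N", "O", "S", "P", "NA", "CL", "K", "MG", "CA", "ZN", "F")
  nm[max.col(-abs(outer(mass, unname(ref), "-")))]
}

# Adjacency list from the bond matrix
bond_adjacency <- function(n_atoms, bonds) {
  adj <- vector("list", n_atoms)
  if (length(bonds) > 0) {
    for (r in seq_len(nrow(bonds))) {
      i <- bonds[r, 1]; j <- bonds[r, 2]
      adj[[i]] <- c(adj[[i]], j)
      adj[[j]] <- c(adj[[j]], i)
    }
  }
  adj
}
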