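# Conformational (topographical) entropy at the united-atom level: dihedral
# angles are discretized into conformers by nearest histogram peak, and the
# entropy is the Shannon entropy over the joint conformer states of all
# dihedrals in a residue.

#' Enumerate heavy-atom dihedrals from the bond graph
#'
#' One dihedral per rotatable heavy-atom central bond b-c: the flanking
#' atoms a and d are the lowest-index heavy neighbors of b and c. Each
#' dihedral is assigned to the residue of the central-bond atoms (the
#' monomer of `b`), so backbone phi/psi/omega quadruples that reach into a
#' bonded neighbor residue are kept; improper-like quadruples are not
#' generated.
#'
#' @param hierarchy An `mcc_hierarchy`.
#' @return data.frame with columns `monomer`, `a`, `b`, `c`, `d` (atom ids).
#' @export
enumerate_dihedrals <- function(hierarchy) {
  atoms <- hierarchy$atoms
  heavy <- !atoms$is_hydrogen
  adj <- hierarchy$adjacency
  heavy_nb <- function(i, excl) {
    nb <- adj[[i]]
    sort(nb[heavy[nb] & nb != excl])
  }
  rows <- list()
  bonds <- hierarchy$bonds
  for (r in seq_len(nrow(bonds))) {
    b <- bonds[r, 1]; c_ <- bonds[r, 2]
    if (!heavy[b] || !heavy[c_]) next
    an <- heavy_nb(b, c_)
    dn <- heavy_nb(c_, b)
    if (length(an) == 0 || length(dn) == 0) next
    rows[[length(rows) + 1]] <- data.frame(
      monomer = atoms$monomer[b], a = an[1], b = b, c = c_, d = dn[1])
  }
  if (length(rows) == 0)
    return(data.frame(monomer = integer(0), a = integer(0), b = integer(0),
                      c = integer(0), d = integer(0)))
  do.call(rbind, rows)
}

#' Dihedral angle time series
#'
#' @param frames An `mcc_frames` object (molecules whole).
#' @param dihedrals data.frame with atom-id columns `a`, `b`, `c`, `d`
#'   (e.g. from [enumerate_dihedrals()]).
#' @return Matrix `[n_frames, n_dihedrals]` of angles in degrees,
#'   wrapped to `[-180, 180)`.
#' @export
dihedral_series <- function(frames, dihedrals) {
  n_d <- nrow(dihedrals)
  out <- matrix(NA_real_, frames$n_frames, n_d)
  for (f in seq_len(frames$n_frames)) {
    xyz <- frame_mat(frames$coords, f)
    for (j in seq_len(n_d)) {
      out[f, j] <- dihedral_angle(xyz[dihedrals$a[j], ], xyz[dihedrals$b[j], ],
                                  xyz[dihedrals$c[j], ], xyz[dihedrals$d[j], ])
    }
  }
  out
}

#' Assign conformers to a dihedral-angle series
#'
#' A circular histogram with 30-degree bins is built over `[-180, 180)`;
#' peaks are bins strictly greater than both circular neighbors (plateaus
#' merge to the lower bin index), and every frame is labeled by the peak
#' center nearest in circular distance. With a single occupied well the
#' whole series maps to one conformer.
#'
#' @param angles Numeric vector of dihedral angles in degrees.
#' @param bin_width Histogram bin width in degrees (default 30).
#' @return List with `peaks` (peak centers, degrees), `labels` (per-frame
#'   peak index) and `counts` (bin counts).
#' @export
find_conformers <- function(angles, bin_width = 30) {
  if (length(angles) == 0) stop("empty dihedral series")
  angles <- wrap180(angles)
  n_bins <- round(360 / bin_width)
  bin <- floor((angles + 180) / bin_width) + 1
  bin[bin > n_bins] <- 1L
  counts <- tabulate(bin, nbins = n_bins)
  # circular runs of equal counts; a run is a peak if it rises from the bin
  # before it and falls to the bin after it, and is marked at its lowest
  # bin index (plateau merge rule)
  run_id <- cumsum(c(TRUE, counts[-1] != counts[-n_bins]))
  if (counts[1] == counts[n_bins] && max(run_id) > 1)
    run_id[run_id == max(run_id)] <- 1L
  is_peak <- logical(n_bins)
  for (g in unique(run_id)) {
    members <- which(run_id == g)
    # circular neighbors outside the run must all be strictly lower
    outside <- setdiff(seq_len(n_bins), members)
    if (length(outside) == 0) { is_peak[1] <- TRUE; break }
    nb <- unique(c(((members - 2) %% n_bins) + 1, (members %% n_bins) + 1))
    nb <- intersect(nb, outside)
    if (all(counts[members[1]] > counts[nb]))
      is_peak[min(members)] <- TRUE
  }
  if (!any(is_peak)) is_peak[which.max(counts)] <- TRUE
  centers <- -180 + (which(is_peak) - 0.5) * bin_width
  d <- abs(outer(angles, centers, "-"))
  d <- pmin(d, 360 - d)
  labels <- max.col(-d, ties.method = "first")
  list(peaks = centers, labels = labels, counts = counts)
}

#' Joint conformer-state trace of a residue
#'
#' @param series Angle matrix `[n_frames, n_dihedrals]` for the residue's
#'   dihedrals.
#' @param bin_width Passed to [find_conformers()].
#' @return List with `states` (per-frame joint-state label strings), `p`
#'   (named state probabilities) and `n_conf` (number of unique states).
#' @export
conformer_states <- function(series, bin_width = 30) {
  labs <- apply(series, 2, function(a) find_conformers(a, bin_width)$labels)
  if (is.null(dim(labs))) labs <- matrix(labs, ncol = ncol(series))
  states <- apply(labs, 1, paste, collapse = "|")
  p <- table(states) / length(states)
  list(states = states, p = as.numeric(p), n_conf = length(p))
}

#' Topographical (conformational) entropy of a state distribution
#'
#' `S = -kB * sum_i p_i log p_i` over the joint conformer states, in molar
#' units (J/K/mol).
#'
#' @param p State probabilities (will be normalized), or the output of
#'   [conformer_states()].
#' @return Entropy in J/K/mol.
#' @export
topographical_entropy <- function(p) {
  if (is.list(p)) p <- p$p
  p <- p[p > 0]
  p <- p / sum(p)
  -mcc_constants$R * sum(p * log(p))
}

#' Per-residue conformational entropy of a trajectory
#'
#' @param frames An `mcc_frames` object.
#' @param hierarchy An `mcc_hierarchy`.
#' @param bin_width Histogram bin width in degrees.
#' @return data.frame (`monomer`, `n_dihedrals`, `n_conf`, `S_topo`
#'   in J/K/mol). Residues without heavy-atom dihedrals get `S_topo = 0`.
#' @export
conformational_entropy <- function(frames, hierarchy, bin_width = 30) {
  dih <- enumerate_dihedrals(hierarchy)
  prot <- hierarchy$monomers$id[hierarchy$monomers$kind == "protein_residue"]
  out <- data.frame(monomer = prot, n_dihedrals = 0L, n_conf = 1L,
                    S_topo = 0)
  if (nrow(dih) == 0) return(out)
  series_all <- dihedral_series(frames, dih)
  for (i in seq_along(prot)) {
    j <- which(dih$monomer == prot[i])
    if (length(j) == 0) next
    cs <- conformer_states(series_all[, j, drop = FALSE], bin_width)
    out$n_dihedrals[i] <- length(j)
    out$n_conf[i] <- cs$n_conf
    out$S_topo[i] <- topographical_entropy(cs)
  }
  out
}
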