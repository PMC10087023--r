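# Reporting layer: standardized feature covariance, referenced per-residue
# thermodynamics against capped-amino-acid baselines, bonded-neighbor
# stabilization matrices, hydrophobicity ranking from water free energy,
# and secondary-structure grouping of hydration water.

AA3 <- c("ALA", "ARG", "ASN", "ASP", "CYS", "GLN", "GLU", "GLY", "HIS",
         "ILE", "LEU", "LYS", "MET", "PHE", "PRO", "SER", "THR", "TRP",
         "TYR", "VAL")

SS_CLASSES <- c("bridge", "coil", "extended", "turn", "310helix", "ahelix")

#' Standardized feature covariance matrix
#'
#' Each feature column is normalized to mean zero and population standard
#' deviation one, and the covariance `cov(X, Y) = (1/N) sum (X_i - mean(X))
#' (Y_i - mean(Y))` is computed on the standardized columns, so entries lie
#' in `[-1, 1]` with exact 1 on the diagonal. Constant columns carry no
#' signal and are dropped with a warning.
#'
#' @param features Numeric data.frame or matrix, one row per residue.
#' @return Symmetric covariance matrix of the retained columns.
#' @export
feature_covariance <- function(features) {
  X <- as.matrix(features)
  if (nrow(X) < 2) stop("need at least 2 rows for a covariance")
  n <- nrow(X)
  sds <- sqrt(colMeans(X^2) - colMeans(X)^2)
  keep <- sds > 0
  if (any(!keep))
    warning("dropping constant feature column(s): ",
            paste(colnames(X)[!keep], collapse = ", "))
  X <- X[, keep, drop = FALSE]
  Z <- scale(X, center = TRUE, scale = sds[keep])
  cv <- crossprod(Z) / n
  diag(cv) <- 1
  cv
}

#' Reference residue thermodynamics against capped-amino-acid baselines
#'
#' Subtracts, per residue, the baseline enthalpy/entropy of the matching
#' single solvated capped amino acid. Terminal residues (first and last of
#' each chain) are excluded; residues whose type has no baseline row are
#' skipped with a message.
#'
#' @param residues data.frame with columns `monomer`, `resname`, `polymer`,
#'   `H` (kJ/mol), `S` (J/K/mol), and optionally more.
#' @param baselines data.frame with columns `resname`, `H`, `S` (same units),
#'   one row per residue type, e.g. read from a baselines TSV.
#' @param temperature Temperature in K.
#' @return data.frame (`monomer`, `resname`, `dH`, `dS`, `dTS`, `dG`), plus
#'   per-protein means as attribute `per_polymer`.
#' @export
referenced_deltas <- function(residues, baselines, temperature) {
  res <- residues
  # drop chain-terminal residues
  term <- unlist(lapply(split(res$monomer, res$polymer), function(m)
    c(min(m), max(m))))
  res <- res[!(res$monomer %in% term), , drop = FALSE]
  hit <- match(res$resname, baselines$resname)
  if (anyNA(hit)) {
    message("no baseline for type(s): ",
            paste(unique(res$resname[is.na(hit)]), collapse = ", "),
            "; residues skipped")
    res <- res[!is.na(hit), , drop = FALSE]
    hit <- hit[!is.na(hit)]
  }
  out <- data.frame(
    monomer = res$monomer, resname = res$resname, polymer = res$polymer,
    dH = res$H - baselines$H[hit],
    dS = res$S - baselines$S[hit],
    stringsAsFactors = FALSE
  )
  out$dTS <- temperature * out$dS / 1000
  out$dG <- out$dH - out$dTS
  per_pol <- do.call(rbind, lapply(split(out, out$polymer), function(d)
    data.frame(polymer = d$polymer[1], dTS = mean(d$dTS), dH = mean(d$dH),
               dG = mean(d$dG), n = nrow(d))))
  attr(out, "per_polymer") <- per_pol
  out
}

#' Bonded-neighbor stabilization matrices
#'
#' For every bonded residue pair in each chain, the referenced free-energy
#' change `dG` of residue n is attributed to (type of n, type of n-1) in the
#' N-side matrix and (type of n, type of n+1) in the C-side matrix; cells
#' are the mean `dG` with occurrence counts. Unobserved pairs have count 0
#' and `NA` mean.
#'
#' @param deltas Output of [referenced_deltas()].
#' @param sequences List (per polymer id, names matching `deltas$polymer`)
#'   of residue-type vectors in chain order, with the corresponding monomer
#'   ids as names.
#' @return List with `N_side`, `C_side` (mean dG matrices, rows = residue
#'   type, columns = neighbor type) and `counts_N`, `counts_C`.
#' @export
neighbor_effect_matrix <- function(deltas, sequences) {
  types <- sort(unique(unlist(sequences)))
  mk <- function() matrix(0, length(types), length(types),
                          dimnames = list(types, types))
  sum_n <- mk(); cnt_n <- mk(); sum_c <- mk(); cnt_c <- mk()
  for (p in names(sequences)) {
    seq_types <- sequences[[p]]
    mon_ids <- as.integer(names(seq_types))
    dg <- deltas$dG[match(mon_ids, deltas$monomer)]
    for (n in seq_along(seq_types)) {
      if (is.na(dg[n])) next
      if (n > 1) {  # N-side neighbor is residue n-1
        sum_n[seq_types[n], seq_types[n - 1]] <-
          sum_n[seq_types[n], seq_types[n - 1]] + dg[n]
        cnt_n[seq_types[n], seq_types[n - 1]] <-
          cnt_n[seq_types[n], seq_types[n - 1]] + 1
      }
      if (n < length(seq_types)) {  # C-side neighbor is residue n+1
        sum_c[seq_types[n], seq_types[n + 1]] <-
          sum_c[seq_types[n], seq_types[n + 1]] + dg[n]
        cnt_c[seq_types[n], seq_types[n + 1]] <-
          cnt_c[seq_types[n], seq_types[n + 1]] + 1
      }
    }
  }
  list(N_side = ifelse(cnt_n > 0, sum_n / cnt_n, NA),
       C_side = ifelse(cnt_c > 0, sum_c / cnt_c, NA),
       counts_N = cnt_n, counts_C = cnt_c)
}

#' Hydrophobicity ranking from hydration-water free energy
#'
#' Amino-acid types are ordered by the free energy of the water molecules
#' nearest their side chains, most stable (lowest G) first; the rank index
#' HR increases with hydrophobicity. Ties break alphabetically.
#'
#' @param water_g Named numeric vector: per-type water free energy (kJ/mol).
#'   Waters nearest capping groups or ions must already be excluded.
#' @return data.frame (`resname`, `G_water`, `HR`).
#' @export
hydrophobicity_rank <- function(water_g) {
  ord <- order(water_g, names(water_g))
  data.frame(resname = names(water_g)[ord], G_water = as.numeric(water_g[ord]),
             HR = seq_along(water_g), stringsAsFactors = FALSE)
}

#' Group hydration-water thermodynamics by secondary structure
#'
#' Waters are attributed to the secondary-structure class of their nearest
#' residue; per class the water-count-weighted mean TS, H, G and the residue
#' and water percentages are reported. Residues without a label fall into
#' class `"other"`.
#'
#' @param water_table data.frame per water group (`nearest_monomer`, `TS`,
#'   `H`, `G`, `N` waters in the group; kJ/mol).
#' @param ss_labels data.frame (`monomer`, `class`), e.g. read from a
#'   STRIDE/DSSP-style per-residue label TSV.
#' @param all_residues Monomer ids of all protein residues (for the residue
#'   percentage).
#' @return data.frame (`class`, `TS`, `H`, `G`, `pct_residues`,
#'   `pct_waters`); empty classes are omitted.
#' @export
secondary_structure_grouping <- function(water_table, ss_labels,
                                         all_residues) {
  lab_of <- function(m) {
    i <- match(m, ss_labels$monomer)
    ifelse(is.na(i), "other", ss_labels$class[i])
  }
  wt <- water_table
  wt$class <- lab_of(wt$nearest_monomer)
  res_class <- lab_of(all_residues)
  if (any(res_class == "other"))
    message(sum(res_class == "other"), " residue(s) without a secondary-",
            "structure label -> class 'other'")
  agg <- lapply(split(wt, wt$class), function(d) data.frame(
    class = d$class[1],
    TS = sum(d$TS * d$N) / sum(d$N),
    H = sum(d$H * d$N) / sum(d$N),
    G = sum(d$G * d$N) / sum(d$N),
    pct_residues = 100 * sum(res_class == d$class[1]) / length(res_class),
    pct_waters = 100 * sum(d$N) / sum(wt$N)))
  out <- do.call(rbind, agg)
  rownames(out) <- NULL
  out
}

#' Per-residue side-chain RMSD versus a reference structure
#'
#' Aligns each frame onto the reference coordinates over all heavy atoms
#' (Kabsch superposition via bio3d), then reports the mean-over-frames RMSD
#' of each residue's side-chain heavy atoms.
#'
#' @param frames An `mcc_frames` object (molecules whole).
#' @param hierarchy An `mcc_hierarchy`.
#' @param ref Reference coordinates `[n_atoms, 3]` (default: first frame).
#' @return data.frame (`monomer`, `rmsd` in Angstrom); residues without
#'   side-chain heavy atoms get `NA`.
#' @export
residue_rmsd <- function(frames, hierarchy, ref = NULL) {
  atoms <- hierarchy$atoms
  ref <- ref %||% frame_mat(frames$coords, 1)
  heavy <- which(!atoms$is_hydrogen)
  bb_names <- c("N", "CA", "C", "O")
  prot <- hierarchy$monomers$id[hierarchy$monomers$kind == "protein_residue"]
  side <- lapply(prot, function(m)
    which(atoms$monomer == m & !atoms$is_hydrogen &
            !(atoms$name %in% bb_names)))
  acc <- numeric(length(prot))
  fixed <- as.numeric(t(ref))
  h_xyz <- as.vector(rbind(3 * heavy - 2, 3 * heavy - 1, 3 * heavy))
  for (f in seq_len(frames$n_frames)) {
    mob <- as.numeric(t(frame_mat(frames$coords, f)))
    fit <- bio3d::fit.xyz(fixed, mob, fixed.inds = h_xyz, mobile.inds = h_xyz)
    fit <- matrix(fit, ncol = 3, byrow = TRUE)
    for (i in seq_along(prot)) {
      idx <- side[[i]]
      if (length(idx) == 0) { acc[i] <- NA_real_; next }
      acc[i] <- acc[i] + sqrt(mean(rowSums((fit[idx, , drop = FALSE] -
                                              ref[idx, , drop = FALSE])^2)))
    }
  }
  data.frame(monomer = prot, rmsd = acc / frames$n_frames)
}

#' Read a per-residue secondary-structure label file
#'
#' Two tab-separated columns: `monomer` (residue id) and `class` (one of
#' bridge, coil, extended, turn, 310helix, ahelix, or any label).
#'
#' @param path Label file path.
#' @return data.frame (`monomer`, `class`).
#' @export
read_ss_labels <- function(path) {
  d <- read_tsv_file(path)
  if (!all(c("monomer", "class") %in% names(d)))
    stop("secondary-structure file needs columns monomer, class")
  d
}
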