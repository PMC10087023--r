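# Parameter-free coordination shells by the relative angular distance (RAD)
# criterion, topological hydrogen bonds, and proximity grouping of water.
#
# RAD operates at the united-atom level with the UA centered on its heavy
# atom: a sorted neighbor j belongs to the shell of i unless some closer
# neighbor k blocks it, i.e. unless 1/r_ij^2 <= (1/r_ik^2) * cos(theta_jik),
# where theta_jik is the angle at i between j and k.

#' RAD coordination shell of one united atom
#'
#' @param xyz Matrix `[n_ua, 3]` of UA center (heavy-atom) positions.
#' @param i Index of the central UA.
#' @param box Box lengths (3-vector) for minimum-image distances, or NULL.
#' @param cutoff Candidate pre-filter distance in Angstrom (default 8). The
#'   cutoff only trims the sorted candidate list; it is generous enough not
#'   to change shells for condensed-phase systems.
#' @param blockers `"all_closer"` (default) tests every closer neighbor as a
#'   potential blocker; `"accepted"` only already-accepted ones.
#' @return List with `ids` (shell UA indices ordered by distance) and `dists`.
#' @export
rad_shell <- function(xyz, i, box = NULL, cutoff = 8,
                      blockers = c("all_closer", "accepted")) {
  blockers <- match.arg(blockers)
  dx <- sweep(xyz, 2, xyz[i, ])
  dx <- min_image(dx, box)
  r <- sqrt(rowSums(dx * dx))
  r[i] <- Inf
  cand <- which(r <= cutoff)
  if (any(r[cand] < 1e-8))
    stop("coincident UA positions at center ", i)
  cand <- cand[order(r[cand])]
  if (length(cand) == 0) return(list(ids = integer(0), dists = numeric(0)))
  U <- dx[cand, , drop = FALSE] / r[cand]
  rc <- r[cand]
  inv2 <- 1 / rc^2
  keep <- logical(length(cand))
  keep[1] <- TRUE  # nearest neighbor can never be blocked
  for (j in seq_along(cand)[-1]) {
    prior <- if (blockers == "all_closer") seq_len(j - 1) else which(keep[seq_len(j - 1)])
    cosjk <- U[prior, , drop = FALSE] %*% U[j, ]
    keep[j] <- all(inv2[j] > inv2[prior] * cosjk)
  }
  list(ids = cand[keep], dists = rc[keep])
}

#' RAD shells for every united atom over trajectory frames
#'
#' @param frames An `mcc_frames` object (molecules should be whole).
#' @param hierarchy An `mcc_hierarchy`.
#' @param frame_idx Frames to process (default all).
#' @param cutoff,blockers Passed to [rad_shell()].
#' @return An object of class `mcc_shellmap`: list with `frames` (the frame
#'   indices) and `shells`, a list (per frame) of lists (per UA) with `ids`
#'   and `dists`.
#' @export
rad_shells <- function(frames, hierarchy, frame_idx = NULL, cutoff = 8,
                       blockers = "all_closer") {
  frame_idx <- frame_idx %||% seq_len(frames$n_frames)
  heavy <- hierarchy$ua$heavy
  out <- vector("list", length(frame_idx))
  for (k in seq_along(frame_idx)) {
    f <- frame_idx[k]
    xyz <- matrix(frames$coords[f, heavy, ], ncol = 3)
    bx <- frames$box[f, ]
    out[[k]] <- lapply(seq_len(nrow(xyz)), function(i)
      rad_shell(xyz, i, box = bx, cutoff = cutoff, blockers = blockers))
  }
  structure(list(frames = frame_idx, shells = out), class = "mcc_shellmap")
}

#' Topological hydrogen-bond assignment
#'
#' Each donor hydrogen (positive partial charge) is assigned to at most one
#' acceptor: the negatively charged atom, within a united atom of the donor
#' UA's RAD shell, for which the electrostatic score qD*qA/r^2 is most
#' negative. Ties break to the lowest atom index. A hydrogen with no
#' candidate acceptor forms no bond.
#'
#' @param frames An `mcc_frames` object.
#' @param hierarchy An `mcc_hierarchy`.
#' @param shellmap An `mcc_shellmap` from [rad_shells()].
#' @return data.frame with columns `frame`, `hydrogen` (atom id), `donor_ua`,
#'   `acceptor_atom`, `acceptor_ua`, `score`.
#' @export
assign_hbonds <- function(frames, hierarchy, shellmap) {
  atoms <- hierarchy$atoms
  donors <- which(atoms$is_hydrogen & atoms$charge > 0)
  recs <- list()
  for (k in seq_along(shellmap$frames)) {
    f <- shellmap$frames[k]
    xyz <- frame_mat(frames$coords, f)
    bx <- frames$box[f, ]
    shells_f <- shellmap$shells[[k]]
    for (h in donors) {
      dua <- atoms$ua[h]
      shell_uas <- shells_f[[dua]]$ids
      if (length(shell_uas) == 0) next
      acc <- which(atoms$ua %in% shell_uas & atoms$charge < 0)
      if (length(acc) == 0) next
      r <- mi_dist(xyz[h, ], xyz[acc, , drop = FALSE], bx)
      score <- atoms$charge[h] * atoms$charge[acc] / r^2
      best <- acc[order(score, acc)[1]]
      recs[[length(recs) + 1]] <- data.frame(
        frame = f, hydrogen = h, donor_ua = dua,
        acceptor_atom = best, acceptor_ua = atoms$ua[best],
        score = min(score))
    }
  }
  if (length(recs) == 0)
    return(data.frame(frame = integer(0), hydrogen = integer(0),
                      donor_ua = integer(0), acceptor_atom = integer(0),
                      acceptor_ua = integer(0), score = numeric(0)))
  do.call(rbind, recs)
}

#' Group waters by their nearest non-water united atom
#'
#' Implements the proximity criterion: each water whose RAD shell contains at
#' least one non-water UA is labeled by the nearest such UA and the residue
#' containing it; waters with no solute UA in shell are labeled bulk
#' (`nearest_monomer = NA`). When the shell contains UAs of two or more
#' residues, residue-pair labels are emitted for all such pairs.
#'
#' @param frames An `mcc_frames` object.
#' @param hierarchy An `mcc_hierarchy`.
#' @param shellmap An `mcc_shellmap`.
#' @return List with `waters`: data.frame (`frame`, `water` monomer id,
#'   `water_ua`, `nearest_ua`, `nearest_dist`, `nearest_monomer`,
#'   `second_monomer`) and `pairs`: data.frame (`frame`, `water`, `res_i`,
#'   `res_j`) with `res_i < res_j`.
#' @export
nearest_solute_grouping <- function(frames, hierarchy, shellmap) {
  ua <- hierarchy$ua
  mon <- hierarchy$monomers
  water_mon <- which(mon$kind == "water")
  water_ua <- ua$id[ua$monomer %in% water_mon]
  is_water_ua <- ua$monomer %in% water_mon
  rows <- list(); prs <- list()
  for (k in seq_along(shellmap$frames)) {
    f <- shellmap$frames[k]
    shells_f <- shellmap$shells[[k]]
    for (w in water_ua) {
      sh <- shells_f[[w]]
      solute <- which(!is_water_ua[sh$ids])
      if (length(solute) == 0) {
        rows[[length(rows) + 1]] <- data.frame(
          frame = f, water = ua$monomer[w], water_ua = w,
          nearest_ua = NA_integer_, nearest_dist = NA_real_,
          nearest_monomer = NA_integer_, second_monomer = NA_integer_)
        next
      }
      ids <- sh$ids[solute]; dd <- sh$dists[solute]
      mon_of <- ua$monomer[ids]
      # ties in distance break to the lowest residue id
      ord <- order(dd, mon_of)
      near_ua <- ids[ord[1]]
      near_mon <- mon_of[ord[1]]
      other <- ord[mon_of[ord] != near_mon]
      second <- if (length(other) > 0) mon_of[other[1]] else NA_integer_
      rows[[length(rows) + 1]] <- data.frame(
        frame = f, water = ua$monomer[w], water_ua = w,
        nearest_ua = near_ua, nearest_dist = dd[ord[1]],
        nearest_monomer = near_mon, second_monomer = second)
      res <- sort(unique(mon_of))
      if (length(res) >= 2) {
        cmb <- utils::combn(res, 2)
        prs[[length(prs) + 1]] <- data.frame(
          frame = f, water = ua$monomer[w],
          res_i = cmb[1, ], res_j = cmb[2, ])
      }
    }
  }
  waters <- if (length(rows) > 0) do.call(rbind, rows) else
    data.frame(frame = integer(0), water = integer(0), water_ua = integer(0),
               nearest_ua = integer(0), nearest_dist = numeric(0),
               nearest_monomer = integer(0), second_monomer = integer(0))
  pairs <- if (length(prs) > 0) do.call(rbind, prs) else
    data.frame(frame = integer(0), water = integer(0), res_i = integer(0),
               res_j = integer(0))
  list(waters = waters, pairs = pairs)
}

#' Shell-derived counts per residue
#'
#' `Nc` is the per-UA mean RAD shell size; `NWc` the mean number of distinct
#' water molecules having a UA of the residue in their shell; `NRc` the mean
#' number of protein UAs from other residues found in the shells of the
#' residue's UAs.
#'
#' @param hierarchy An `mcc_hierarchy`.
#' @param shellmap An `mcc_shellmap`.
#' @param grouping Output of [nearest_solute_grouping()].
#' @return List with `ua_nc` (per-UA mean shell size) and `residues`
#'   data.frame (`monomer`, `NWc`, `NRc`).
#' @export
shell_counts <- function(hierarchy, shellmap, grouping) {
  ua <- hierarchy$ua
  mon <- hierarchy$monomers
  n_fr <- length(shellmap$frames)
  nc <- rowMeans(vapply(shellmap$shells, function(sf)
    lengths(lapply(sf, `[[`, "ids")), numeric(nrow(ua))))
  prot_mon <- which(mon$kind == "protein_residue")
  is_water_ua <- mon$kind[ua$monomer] == "water"
  nwc <- nrc <- setNames(numeric(length(prot_mon)), prot_mon)
  for (k in seq_len(n_fr)) {
    sf <- shellmap$shells[[k]]
    for (m in prot_mon) {
      uas_m <- ua$id[ua$monomer == m]
      nb <- unique(unlist(lapply(sf[uas_m], `[[`, "ids")))
      nb <- setdiff(nb, uas_m)
      nwc[as.character(m)] <- nwc[as.character(m)] +
        length(unique(ua$monomer[nb[is_water_ua[nb]]]))
      nrc[as.character(m)] <- nrc[as.character(m)] +
        sum(mon$kind[ua$monomer[nb]] == "protein_residue")
    }
  }
  list(ua_nc = nc,
       residues = data.frame(monomer = prot_mon, NWc = nwc / n_fr,
                             NRc = nrc / n_fr))
}

#' Export a shell map as TSV
#'
#' One row per (frame, center UA) with the ordered neighbor list.
#' @param shellmap An `mcc_shellmap`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_shellmap_tsv <- function(shellmap, path) {
  rows <- list()
  for (k in seq_along(shellmap$frames)) {
    sf <- shellmap$shells[[k]]
    rows[[k]] <- data.frame(
      frame = shellmap$frames[k], center = seq_along(sf),
      neighbors = vapply(sf, function(s) paste(s$ids, collapse = ","), ""))
  }
  write_tsv_file(do.call(rbind, rows), path)
}
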