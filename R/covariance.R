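# Force and torque covariance accumulation.
#
# At each level the matrix elements are mass-weighted net forces
# F_u / sqrt(M_u) for translations and inertia-weighted torques
# tau_u / sqrt(I_u,axis) for rotations, expressed in the level's coordinate
# frames and accumulated as running means of outer products over frames.
# Covariances are block matrices over the units of a level, so inter-unit
# correlations at the same level are captured. Moments of inertia are
# computed per frame about the unit origin in the local frame.

# torque about `origin` expressed in `axes` (rows), with per-axis moments of
# inertia of the atom set
torque_inertia <- function(r, F, m, axes) {
  tau <- c(sum(r[, 2] * F[, 3] - r[, 3] * F[, 2]),
           sum(r[, 3] * F[, 1] - r[, 1] * F[, 3]),
           sum(r[, 1] * F[, 2] - r[, 2] * F[, 1]))
  r_loc <- r %*% t(axes)
  r2 <- rowSums(r_loc * r_loc)
  I <- vapply(1:3, function(a) sum(m * (r2 - r_loc[, a]^2)), 0)
  list(tau = as.numeric(axes %*% tau), I = I)
}

# kept rotational axis indices for a unit
# frame_kind "principal": smallest-moment axis (3) lies along a linear unit
# frame_kind "ua": the x axis (1) lies along the bond of a linear UA
kept_axes <- function(geometry, frame_kind) {
  switch(geometry,
         nonlinear = 1:3,
         linear = if (frame_kind == "ua") 2:3 else 1:2,
         point = integer(0))
}

#' Accumulate force and torque covariance matrices for one level
#'
#' Builds the running-mean covariance of mass-weighted net forces and
#' inertia-weighted torques over trajectory frames for a set of units:
#' * `level = "polymer"`: one whole molecule; principal-axes frame at the
#'   center of mass; 3 translational + up to 3 rotational components.
#' * `level = "monomer"`: all residues of one polymer; translations in the
#'   polymer principal axes, rotations in each residue's backbone frame.
#' * `level = "ua"`: all united atoms of one monomer; translations in the
#'   residue backbone frame, rotations in each UA's local frame with
#'   3/2/0 axes for nonlinear/linear/point UAs.
#' * `level = "water"`: each water molecule is its own single-unit system
#'   (principal axes, 3+3 modes, no rigid-body removal downstream); samples
#'   from all waters in `waters` and all frames are pooled into one pair of
#'   3x3 matrices so small populations converge.
#'
#' @param frames An `mcc_frames` object with forces (molecules whole).
#' @param hierarchy An `mcc_hierarchy`.
#' @param level One of `"polymer"`, `"monomer"`, `"ua"`, `"water"`.
#' @param polymer Polymer id (levels `"polymer"` and `"monomer"`).
#' @param monomer Monomer id (level `"ua"`).
#' @param waters Water monomer ids to pool (level `"water"`, default all).
#' @param frame_idx Frames to use (default all).
#' @return An object of class `mcc_covacc`: list with `fcov` (force
#'   covariance, `(kJ/mol/A)^2/amu`), `tcov` (torque covariance,
#'   `(kJ/mol)^2/(amu A^2)`), `level`, `unit_ids`, `rot_units` (unit id per
#'   torque row), `n_units`, `n_samples`.
#' @export
accumulate_covariance <- function(frames, hierarchy,
                                  level = c("polymer", "monomer", "ua",
                                            "water"),
                                  polymer = NULL, monomer = NULL,
                                  waters = NULL, frame_idx = NULL) {
  level <- match.arg(level)
  if (is.null(frames$forces)) stop("FrameBatch has no forces")
  frame_idx <- frame_idx %||% seq_len(frames$n_frames)
  atoms <- hierarchy$atoms
  masses <- atoms$mass

  if (level == "water") {
    mon <- hierarchy$monomers
    waters <- waters %||% mon$id[mon$kind == "water"]
    if (length(waters) == 0) stop("no water monomers to accumulate")
    idx_list <- unit_atoms(hierarchy, "monomer")[as.character(waters)]
    sF <- matrix(0, 3, 3); sT <- matrix(0, 3, 3); n <- 0L
    for (f in frame_idx) {
      xyz <- frame_mat(frames$coords, f)
      Fm <- frame_mat(frames$forces, f)
      for (idx in idx_list) {
        pf <- principal_frame(xyz[idx, , drop = FALSE], masses[idx])
        fv <- as.numeric(pf$axes %*% colSums(Fm[idx, , drop = FALSE])) /
          sqrt(sum(masses[idx]))
        ti <- torque_inertia(sweep(xyz[idx, , drop = FALSE], 2, pf$origin),
                             Fm[idx, , drop = FALSE], masses[idx], pf$axes)
        tv <- ti$tau / sqrt(ti$I)
        sF <- sF + tcrossprod(fv)
        sT <- sT + tcrossprod(tv)
        n <- n + 1L
      }
    }
    return(structure(list(level = level, unit_ids = waters,
                          fcov = sF / n, tcov = sT / n,
                          rot_units = rep(waters[1], 3), n_units = 1L,
                          n_samples = n), class = "mcc_covacc"))
  }

  # resolve the unit atom sets and static rotational-mode bookkeeping
  if (level == "polymer") {
    polymer <- polymer %||% hierarchy$polymers$id[1]
    unit_idx <- list(which(atoms$polymer == polymer))
    unit_ids <- polymer
  } else if (level == "monomer") {
    polymer <- polymer %||% hierarchy$polymers$id[1]
    mon_ids <- hierarchy$monomers$id[hierarchy$monomers$polymer == polymer]
    unit_idx <- unit_atoms(hierarchy, "monomer")[as.character(mon_ids)]
    unit_ids <- mon_ids
  } else {
    if (is.null(monomer)) stop("level='ua' needs a monomer id")
    ua_ids <- hierarchy$ua$id[hierarchy$ua$monomer == monomer]
    unit_idx <- unit_atoms(hierarchy, "ua")[as.character(ua_ids)]
    unit_ids <- ua_ids
  }
  n_units <- length(unit_idx)

  x0 <- frame_mat(frames$coords, frame_idx[1])
  geom <- vapply(seq_len(n_units), function(u) {
    if (level == "ua") hierarchy$ua$geometry[unit_ids[u]]
    else unit_geometry(x0[unit_idx[[u]], , drop = FALSE])
  }, "")
  frame_kind <- if (level == "ua") "ua" else "principal"
  kept <- lapply(geom, kept_axes, frame_kind = frame_kind)
  rot_units <- rep(unit_ids, lengths(kept))
  dim_t <- length(rot_units)
  dim_f <- 3L * n_units

  M_u <- vapply(unit_idx, function(idx) sum(masses[idx]), 0)
  # reference atom per UA: first bonded heavy neighbor, to orient the
  # perpendicular axes of linear UAs consistently with the structure
  ua_ref <- NULL
  if (level == "ua") {
    ua_ref <- vapply(unit_ids, function(uid) {
      hv <- hierarchy$ua$heavy[uid]
      nb <- setdiff(hierarchy$adjacency[[hv]], hierarchy$ua_hydrogens[[uid]])
      if (length(nb) > 0) min(nb) else NA_integer_
    }, 0L)
  }
  sF <- matrix(0, dim_f, dim_f)
  sT <- matrix(0, dim_t, dim_t)

  for (f in frame_idx) {
    xyz <- frame_mat(frames$coords, f)
    Fm <- frame_mat(frames$forces, f)
    # translation frame shared across units of the level
    trans_axes <- switch(level,
      polymer = NULL,  # per-unit principal frame below
      monomer = {
        p_idx <- which(atoms$polymer == polymer)
        principal_frame(xyz[p_idx, , drop = FALSE], masses[p_idx])$axes
      },
      ua = {
        mrow <- hierarchy$monomers[monomer, ]
        residue_frame(xyz, unlist(mrow[c("N", "CA", "C")]),
                      which(atoms$monomer == monomer), masses)$axes
      })
    fvec <- numeric(dim_f)
    tvec <- numeric(dim_t)
    tpos <- 0L
    for (u in seq_len(n_units)) {
      idx <- unit_idx[[u]]
      netF <- colSums(Fm[idx, , drop = FALSE])
      rot_fr <- switch(level,
        polymer = principal_frame(xyz[idx, , drop = FALSE], masses[idx]),
        monomer = {
          mrow <- hierarchy$monomers[unit_ids[u], ]
          residue_frame(xyz, unlist(mrow[c("N", "CA", "C")]), idx, masses)
        },
        ua = ua_frame(xyz, hierarchy$ua$heavy[unit_ids[u]],
                      hierarchy$ua_hydrogens[[unit_ids[u]]],
                      ref = if (!is.na(ua_ref[u])) ua_ref[u]))
      tA <- trans_axes %||% rot_fr$axes
      fvec[(3 * u - 2):(3 * u)] <- as.numeric(tA %*% netF) / sqrt(M_u[u])
      ka <- kept[[u]]
      if (length(ka) > 0) {
        ti <- torque_inertia(sweep(xyz[idx, , drop = FALSE], 2, rot_fr$origin),
                             Fm[idx, , drop = FALSE], masses[idx],
                             rot_fr$axes)
        tvec[tpos + seq_along(ka)] <- ti$tau[ka] / sqrt(ti$I[ka])
        tpos <- tpos + length(ka)
      }
    }
    sF <- sF + tcrossprod(fvec)
    if (dim_t > 0) sT <- sT + tcrossprod(tvec)
  }
  n <- length(frame_idx)
  if (n < dim_f)
    warning("fewer samples (", n, ") than force-matrix dimension (", dim_f,
            "); covariance is rank-deficient")
  structure(list(level = level, unit_ids = unit_ids, fcov = sF / n,
                 tcov = sT / n, rot_units = rot_units, n_units = n_units,
                 n_samples = n), class = "mcc_covacc")
}

#' @export
print.mcc_covacc <- function(x, ...) {
  cat("mcc_covacc [", x$level, "]: ", nrow(x$fcov), " force + ",
      nrow(x$tcov), " torque components, ", x$n_samples, " samples\n",
      sep = "")
  invisible(x)
}
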