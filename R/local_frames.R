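# Level-specific local coordinate frames.
#
# Translations and rotations of each unit are expressed in frames tied to
# the structure: whole molecules use mass-weighted principal axes at the
# center of mass; residue rotations use a backbone frame (x along N->C, y
# normal to the N-CA-C plane, z completing the right-handed set); UA
# rotations use the heavy atom as origin with x along the mean covalent
# bond vector to the hydrogens.

# Deterministic, rotation-equivariant sign convention: each of the first
# two axes is oriented toward the first structure vector (atom minus
# origin, in atom order) it is not orthogonal to; the third axis is
# recomputed to keep the set right-handed. Falling back to
# largest-component-positive only when the unit has no usable extent.
fix_axes <- function(A, ref = NULL) {
  for (r in 1:2) {
    s <- 0
    if (!is.null(ref)) {
      d <- as.numeric(ref %*% A[r, ])
      hit <- which(abs(d) > 1e-6)
      if (length(hit) > 0) s <- sign(d[hit[1]])
    }
    if (s == 0) s <- sign(A[r, which.max(abs(A[r, ]))])
    A[r, ] <- s * A[r, ]
  }
  A[3, ] <- cross3(A[1, ], A[2, ])
  A
}

#' Mass-weighted principal-axes frame of a set of atoms
#'
#' @param xyz Matrix `[n, 3]` of positions.
#' @param masses Atom masses (amu).
#' @return List with `origin` (center of mass) and `axes` (3 x 3 matrix,
#'   rows = axes, orthonormal right-handed).
#' @export
principal_frame <- function(xyz, masses) {
  com <- colSums(xyz * masses) / sum(masses)
  r <- sweep(xyz, 2, com)
  I <- diag(3) * sum(masses * rowSums(r * r)) -
    t(r) %*% (r * masses)
  ev <- eigen((I + t(I)) / 2, symmetric = TRUE)
  A <- t(ev$vectors)   # rows = axes, descending moment
  list(origin = com, axes = fix_axes(A, ref = r))
}

#' Backbone local frame of a protein residue
#'
#' Origin is the average of the N, CA, C positions; x is the unit N->C
#' vector, y the unit normal to the N-CA-C plane, z completes the
#' right-handed set. Degenerate (collinear) backbones fall back to the
#' principal-axes frame with a warning.
#'
#' @param xyz Full coordinate matrix `[n_atoms, 3]` of one frame.
#' @param bb Integer vector of the N, CA, C atom indices.
#' @param fallback_atoms Atom indices of the residue, used for the
#'   principal-axes fallback.
#' @param masses Masses for the fallback.
#' @return List with `origin` and `axes`.
#' @export
residue_frame <- function(xyz, bb, fallback_atoms = NULL, masses = NULL) {
  if (anyNA(bb)) return(principal_frame(xyz[fallback_atoms, , drop = FALSE],
                                        masses[fallback_atoms]))
  n <- xyz[bb[1], ]; ca <- xyz[bb[2], ]; c_ <- xyz[bb[3], ]
  origin <- (n + ca + c_) / 3
  x <- c_ - n
  nrm <- cross3(ca - n, c_ - n)
  if (vec_norm(x) < 1e-8 || vec_norm(nrm) < 1e-8) {
    warning("collinear backbone; falling back to principal axes")
    return(principal_frame(xyz[fallback_atoms, , drop = FALSE],
                           masses[fallback_atoms]))
  }
  x <- unit_vec(x)
  y <- unit_vec(nrm)
  list(origin = origin, axes = rbind(x, y, cross3(x, y), deparse.level = 0))
}

#' Local frame of a united atom
#'
#' Origin at the heavy atom. With hydrogens, x is the unit mean of the
#' covalent bond vectors to the hydrogens and y, z are orthogonal
#' completions; without hydrogens (a point UA) the axes are the identity.
#'
#' @param xyz Full coordinate matrix of one frame.
#' @param heavy Heavy-atom index.
#' @param hydrogens Indices of the UA's hydrogens (may be empty).
#' @param ref Optional index of a reference atom (typically the first
#'   bonded heavy neighbor) that fixes the perpendicular axes of a linear
#'   UA in a rotation-equivariant way.
#' @return List with `origin` and `axes`.
#' @export
ua_frame <- function(xyz, heavy, hydrogens, ref = NULL) {
  origin <- xyz[heavy, ]
  if (length(hydrogens) == 0)
    return(list(origin = origin, axes = diag(3)))
  mb <- colMeans(xyz[hydrogens, , drop = FALSE]) - origin
  x <- unit_vec(mb)
  # y from the first hydrogen's bond vector; a single hydrogen lies along
  # x, so the reference atom (or, failing that, a lab axis) breaks the tie
  cands <- rbind(xyz[hydrogens[1], ] - origin,
                 if (!is.null(ref)) xyz[ref, ] - origin)
  perp <- c(0, 0, 0)
  for (r in seq_len(nrow(cands))) {
    perp <- cands[r, ] - sum(cands[r, ] * x) * x
    if (vec_norm(perp) > 1e-8) break
  }
  if (vec_norm(perp) < 1e-8) {
    helper <- diag(3)[which.min(abs(x)), ]
    perp <- cross3(x, helper)
  }
  y <- unit_vec(perp)
  list(origin = origin, axes = rbind(x, y, cross3(x, y), deparse.level = 0))
}

# Geometry class of an arbitrary atom set: point (1 atom), linear
# (collinear within tol), else nonlinear.
unit_geometry <- function(xyz) {
  if (nrow(xyz) == 1) return("point")
  r <- sweep(xyz, 2, colMeans(xyz))
  s <- svd(r, nu = 0, nv = 0)$d
  if (length(s) < 2 || s[2] < 1e-6 * max(s[1], 1e-12)) "linear" else "nonlinear"
}
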