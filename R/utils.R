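# Shared geometry, periodic-boundary and small-I/O helpers.

# Minimum-image displacement(s) dx (matrix n x 3 or vector) for an
# orthorhombic box given as lengths c(Lx, Ly, Lz).
min_image <- function(dx, box) {
  if (is.null(box)) return(dx)
  if (is.matrix(dx)) {
    for (d in 1:3) dx[, d] <- dx[, d] - box[d] * round(dx[, d] / box[d])
    dx
  } else {
    dx - box * round(dx / box)
  }
}

# Minimum-image distances from point p (length 3) to rows of xyz (n x 3).
mi_dist <- function(p, xyz, box) {
  dx <- sweep(xyz, 2, p)
  dx <- min_image(dx, box)
  sqrt(rowSums(dx * dx))
}

vec_norm <- function(v) sqrt(sum(v * v))

unit_vec <- function(v) {
  n <- vec_norm(v)
  if (n < 1e-12) stop("cannot normalize a zero vector")
  v / n
}

cross3 <- function(a, b) {
  c(a[2] * b[3] - a[3] * b[2],
    a[3] * b[1] - a[1] * b[3],
    a[1] * b[2] - a[2] * b[1])
}

# Wrap angles (degrees) into [-180, 180)
wrap180 <- function(a) ((a + 180) %% 360) - 180

# Dihedral angle a-b-c-d in degrees in [-180, 180), standard atan2 form.
dihedral_angle <- function(a, b, c, d) {
  b1 <- b - a; b2 <- c - b; b3 <- d - c
  n1 <- cross3(b1, b2)
  n2 <- cross3(b2, b3)
  x <- sum(n1 * n2)
  y <- sum(cross3(n1, n2) * b2) / vec_norm(b2)
  wrap180(atan2(y, x) * 180 / pi)
}

# Rotation matrix for angle theta (radians) about unit axis u (Rodrigues).
rotation_about_axis <- function(u, theta) {
  u <- unit_vec(u)
  K <- matrix(c(0, u[3], -u[2], -u[3], 0, u[1], u[2], -u[1], 0), 3, 3)
  diag(3) + sin(theta) * K + (1 - cos(theta)) * (K %*% K)
}

read_tsv_file <- function(path, ...) {
  utils::read.table(path, header = TRUE, sep = "\t", stringsAsFactors = FALSE,
                    check.names = FALSE, ...)
}

write_tsv_file <- function(x, path) {
  utils::write.table(x, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# frame f of an [frame, atom, xyz] array as an n_atoms x 3 matrix,
# robust to n_atoms == 1
frame_mat <- function(a, f) matrix(a[f, , ], ncol = 3)
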