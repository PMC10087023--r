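# FrameBatch ingestion: coordinates, forces, box vectors and per-atom
# energies in fixed internal units (Angstrom, kJ/mol, K, amu).
#
# Readers: LAMMPS text dump (custom columns id/x/y/z/fx/fy/fz), DCD via
# bio3d, and a columnar per-atom energy TSV (frame, atom, pe, ke) so that
# fixtures need no MD engine.

#' Load a trajectory into a FrameBatch
#'
#' Reads coordinate and (optionally) force and per-atom-energy streams,
#' checks that they are frame-aligned, applies a stride, and converts to the
#' package's internal units (Angstrom, kJ/mol).
#'
#' @param coords Path to a LAMMPS dump (`.dump`/`.lammpstrj`) carrying
#'   `x y z` columns, or a DCD file (`.dcd`).
#' @param forces Optional path to a LAMMPS dump carrying `fx fy fz` columns.
#'   May be the same file as `coords` if it has both column sets.
#' @param energies Optional path to a per-atom energy TSV with columns
#'   `frame`, `atom`, `pe`, `ke` (1-based frame and atom ids).
#' @param stride Keep every `stride`-th frame (default 1).
#' @param temperature Simulation temperature in K (default 298).
#' @param units `"kj"` (already kJ/mol based; no conversion) or `"real"`
#'   (LAMMPS real units: kcal/mol energies and kcal/mol/A forces, converted
#'   by 4.184).
#' @param box Optional per-frame box lengths (vector of 3 or n_frames x 3
#'   matrix) for formats that do not carry one (DCD without a cell).
#' @return An object of class `mcc_frames`: list with `coords` and `forces`
#'   arrays `[frame, atom, xyz]`, `pe`/`ke` matrices `[frame, atom]`, `box`
#'   matrix `[frame, 3]`, `n_frames`, `n_atoms`, `temperature`.
#' @export
load_frames <- function(coords, forces = NULL, energies = NULL, stride = 1L,
                        temperature = 298, units = c("kj", "real"),
                        box = NULL) {
  units <- match.arg(units)
  scale <- if (units == "real") mcc_constants$kcal else 1

  cd <- read_traj_any(coords)
  xyz <- cd$coords
  if (is.null(xyz)) stop("no coordinate columns found in ", coords)
  frc <- NULL
  if (!is.null(forces)) {
    fd <- if (identical(forces, coords)) cd else read_traj_any(forces)
    frc <- fd$forces
    if (is.null(frc)) stop("no force columns found in ", forces)
    if (dim(frc)[1] != dim(xyz)[1])
      stop("frame-count mismatch: ", dim(xyz)[1], " coordinate frames vs ",
           dim(frc)[1], " force frames")
    if (dim(frc)[2] != dim(xyz)[2])
      stop("atom-count mismatch between coordinate and force streams")
    frc <- frc * scale
  }
  boxes <- cd$box
  if (!is.null(box)) {
    boxes <- if (is.matrix(box)) box else
      matrix(box, nrow = dim(xyz)[1], ncol = 3, byrow = TRUE)
  }
  if (is.null(boxes)) stop("no box information in ", coords,
                           "; supply `box=`")
  if (any(boxes <= 0)) stop("box lengths must be positive")

  pe <- ke <- NULL
  if (!is.null(energies)) {
    en <- read_energy_tsv(energies, n_frames = dim(xyz)[1],
                          n_atoms = dim(xyz)[2])
    pe <- en$pe * scale
    ke <- en$ke * scale
  }

  keep <- seq(1, dim(xyz)[1], by = stride)
  fb <- structure(list(
    coords = xyz[keep, , , drop = FALSE],
    forces = if (!is.null(frc)) frc[keep, , , drop = FALSE],
    pe = if (!is.null(pe)) pe[keep, , drop = FALSE],
    ke = if (!is.null(ke)) ke[keep, , drop = FALSE],
    box = boxes[keep, , drop = FALSE],
    n_frames = length(keep),
    n_atoms = dim(xyz)[2],
    temperature = temperature
  ), class = "mcc_frames")
  fb
}

#' @export
print.mcc_frames <- function(x, ...) {
  cat("mcc_frames:", x$n_frames, "frames x", x$n_atoms, "atoms;",
      if (is.null(x$forces)) "no forces;" else "forces;",
      if (is.null(x$pe)) "no energies;" else "per-atom energies;",
      "T =", x$temperature, "K\n")
  invisible(x)
}

read_traj_any <- function(path) {
  if (grepl("\\.dcd$", path, ignore.case = TRUE)) {
    dcd <- bio3d::read.dcd(path, verbose = FALSE)
    n_fr <- nrow(dcd)
    n_at <- ncol(dcd) / 3
    xyz <- array(NA_real_, c(n_fr, n_at, 3))
    for (d in 1:3) xyz[, , d] <- dcd[, seq(d, by = 3, length.out = n_at)]
    cell <- attr(dcd, "cell")
    box <- if (!is.null(cell)) as.matrix(cell[, 1:3, drop = FALSE]) else NULL
    list(coords = xyz, forces = NULL, box = box)
  } else {
    read_lammps_dump(path)
  }
}

#' Read a LAMMPS text dump
#'
#' Supports orthorhombic `BOX BOUNDS` and an `ITEM: ATOMS` header with an
#' `id` column plus any of `x y z` and `fx fy fz`. Atoms are re-ordered by id
#' within each frame.
#'
#' @param path Dump file path.
#' @return List with `coords` and/or `forces` arrays `[frame, atom, 3]` and
#'   `box` matrix `[frame, 3]`.
#' @export
read_lammps_dump <- function(path) {
  lines <- readLines(path)
  starts <- grep("^ITEM: TIMESTEP", lines)
  if (length(starts) == 0) stop("not a LAMMPS dump: ", path)
  n_fr <- length(starts)
  n_at <- as.integer(lines[starts[1] + 3])
  if (any(as.integer(lines[starts + 3]) != n_at))
    stop("variable atom count across frames is not supported")
  hdr <- strsplit(sub("^ITEM: ATOMS\\s*", "", lines[starts[1] + 8]),
                  "\\s+")[[1]]
  bb <- matrix(scan(text = lines[rep(starts, each = 3) + 5:7],
                    quiet = TRUE), ncol = 2, byrow = TRUE)
  box <- matrix(bb[, 2] - bb[, 1], n_fr, 3, byrow = TRUE)
  body_idx <- rep(starts, each = n_at) + 8 + seq_len(n_at)
  m <- matrix(scan(text = lines[body_idx], quiet = TRUE),
              ncol = length(hdr), byrow = TRUE)
  colnames(m) <- hdr
  # order by atom id within frames
  frame_of <- rep(seq_len(n_fr), each = n_at)
  m <- m[order(frame_of, m[, "id"]), , drop = FALSE]
  grab <- function(cols) {
    if (!all(cols %in% hdr)) return(NULL)
    a <- array(NA_real_, c(n_fr, n_at, 3))
    for (d in 1:3) a[, , d] <- matrix(m[, cols[d]], n_fr, n_at, byrow = TRUE)
    a
  }
  list(coords = grab(c("x", "y", "z")), forces = grab(c("fx", "fy", "fz")),
       box = box)
}

#' Write a LAMMPS-style text dump
#'
#' Inverse of [read_lammps_dump()]; used by the fixture generators so that
#' synthetic trajectories exercise the same I/O path as engine output.
#'
#' @param path Output path.
#' @param coords Array `[frame, atom, 3]`, or NULL to write forces only.
#' @param forces Optional array `[frame, atom, 3]`.
#' @param box Matrix `[frame, 3]` of box lengths, or vector of 3.
#' @return `path`, invisibly.
#' @export
write_lammps_dump <- function(path, coords = NULL, forces = NULL, box) {
  ref <- coords %||% forces
  n_fr <- dim(ref)[1]; n_at <- dim(ref)[2]
  if (!is.matrix(box)) box <- matrix(box, n_fr, 3, byrow = TRUE)
  cols <- c(if (!is.null(coords)) c("x", "y", "z"),
            if (!is.null(forces)) c("fx", "fy", "fz"))
  # flatten to (frame-major) atom rows and assemble all lines in one pass
  flat <- function(a) {
    out <- matrix(NA_real_, n_fr * n_at, 3)
    for (d in 1:3) out[, d] <- as.vector(t(a[, , d]))
    out
  }
  dat <- cbind(if (!is.null(coords)) flat(coords),
               if (!is.null(forces)) flat(forces))
  body <- do.call(paste, c(list(rep(seq_len(n_at), n_fr)),
                           lapply(seq_len(ncol(dat)), function(j)
                             sprintf("%.10g", dat[, j]))))
  header <- rbind("ITEM: TIMESTEP", as.character(seq_len(n_fr) - 1),
                  "ITEM: NUMBER OF ATOMS", as.character(n_at),
                  "ITEM: BOX BOUNDS pp pp pp",
                  sprintf("0.0 %.10g", box[, 1]),
                  sprintf("0.0 %.10g", box[, 2]),
                  sprintf("0.0 %.10g", box[, 3]),
                  paste("ITEM: ATOMS id", paste(cols, collapse = " ")))
  blocks <- rbind(header, matrix(body, n_at, n_fr))
  writeLines(as.vector(blocks), path)
  invisible(path)
}

# Per-atom energy TSV: frame, atom, pe, ke (1-based ids)
read_energy_tsv <- function(path, n_frames, n_atoms) {
  d <- read_tsv_file(path)
  need <- c("frame", "atom", "pe", "ke")
  if (!all(need %in% names(d)))
    stop("energy file must have columns frame, atom, pe, ke ",
         "(tab-separated; see the TSV dialect in ?load_frames)")
  if (max(d$frame) != n_frames)
    stop("frame-count mismatch: energies have ", max(d$frame),
         " frames, coordinates ", n_frames)
  pe <- matrix(NA_real_, n_frames, n_atoms)
  ke <- matrix(NA_real_, n_frames, n_atoms)
  idx <- cbind(d$frame, d$atom)
  pe[idx] <- d$pe
  ke[idx] <- d$ke
  if (anyNA(pe) || anyNA(ke))
    stop("energy file does not cover every (frame, atom) pair")
  list(pe = pe, ke = ke)
}

#' Write the per-atom energy TSV dialect
#'
#' @param path Output path.
#' @param pe,ke Matrices `[frame, atom]` of potential and kinetic energy.
#' @return `path`, invisibly.
#' @export
write_energy_tsv <- function(path, pe, ke) {
  d <- data.frame(frame = rep(seq_len(nrow(pe)), ncol(pe)),
                  atom = rep(seq_len(ncol(pe)), each = nrow(pe)))
  d$pe <- pe[cbind(d$frame, d$atom)]
  d$ke <- ke[cbind(d$frame, d$atom)]
  write_tsv_file(d, path)
}

#' Unwrap molecules across periodic boundaries
#'
#' Makes every bonded molecule whole in each frame by walking the bond graph
#' and shifting each atom to the minimum image relative to its already-placed
#' neighbor. Required before local frames, torques and inertia are computed.
#'
#' @param frames An `mcc_frames` object.
#' @param hierarchy An `mcc_hierarchy`.
#' @return The `mcc_frames` object with unwrapped coordinates.
#' @export
make_whole <- function(frames, hierarchy) {
  n <- frames$n_atoms
  # BFS parent array over the bond graph, one tree per molecule
  parent <- integer(n)
  order_v <- integer(0)
  visited <- logical(n)
  for (root in which(!duplicated(hierarchy$atoms$polymer))) {
    queue <- root; visited[root] <- TRUE; parent[root] <- 0L
    while (length(queue) > 0) {
      v <- queue[1]; queue <- queue[-1]
      order_v <- c(order_v, v)
      for (w in hierarchy$adjacency[[v]]) {
        if (!visited[w]) { visited[w] <- TRUE; parent[w] <- v; queue <- c(queue, w) }
      }
    }
  }
  # isolated atoms (ions) need no unwrapping
  order_v <- c(order_v, which(!visited))
  for (f in seq_len(frames$n_frames)) {
    x <- frame_mat(frames$coords, f)
    bx <- frames$box[f, ]
    for (v in order_v) {
      p <- parent[v]
      if (p > 0) x[v, ] <- x[p, ] + min_image(x[v, ] - x[p, ], bx)
    }
    frames$coords[f, , ] <- x
  }
  frames
}
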