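# Independent oracles and small constructors shared across the suite.

# Brute-force RAD shell: direct enumeration of the blocking inequality,
# independent of the package's sorted/cutoff implementation.
brute_rad <- function(xyz, i, box = NULL) {
  n <- nrow(xyz)
  mi <- function(v) if (is.null(box)) v else v - box * round(v / box)
  rvec <- lapply(seq_len(n), function(j) mi(xyz[j, ] - xyz[i, ]))
  r <- vapply(rvec, function(v) sqrt(sum(v^2)), 0)
  shell <- integer(0)
  for (j in setdiff(seq_len(n), i)) {
    blocked <- FALSE
    for (k in setdiff(seq_len(n), c(i, j))) {
      if (r[k] >= r[j]) next
      cosjk <- sum(rvec[[j]] * rvec[[k]]) / (r[j] * r[k])
      if (!(1 / r[j]^2 > (1 / r[k]^2) * cosjk)) { blocked <- TRUE; break }
    }
    if (!blocked) shell <- c(shell, j)
  }
  shell[order(r[shell])]
}

# Closed-form QHO entropy per mode as a function of x = h nu / (kB T),
# written directly from the formula (J/K/mol).
qho_closed_x <- function(x) {
  8.31446261815324 * (x / (exp(x) - 1) - log(1 - exp(-x)))
}

# frequency giving a prescribed x at temperature T
freq_for_x <- function(x, temperature) {
  x * 1.380649e-23 * temperature / 6.62607015e-34
}

# Tiny topology: one water donor plus two chloride acceptors at given
# positions of the H1 hydrogen's potential acceptors.
donor_acceptor_system <- function(o, h1, h2, cl_pos) {
  n_cl <- nrow(cl_pos)
  atoms <- data.frame(
    index = seq_len(3 + n_cl),
    name = c("O", "H1", "H2", paste0("CL", seq_len(n_cl))),
    element = c("O", "H", "H", rep("CL", n_cl)),
    resid = c(1, 1, 1, seq_len(n_cl) + 1),
    resname = c(rep("WAT", 3), rep("CL-", n_cl)),
    molid = c(1, 1, 1, seq_len(n_cl) + 1),
    mass = c(15.9994, 1.008, 1.008, rep(35.45, n_cl)),
    charge = c(-0.834, 0.417, 0.417, rep(-1, n_cl)),
    stringsAsFactors = FALSE)
  bonds <- matrix(c(1L, 2L, 1L, 3L), ncol = 2, byrow = TRUE,
                  dimnames = list(NULL, c("i", "j")))
  xyz <- rbind(o, h1, h2, cl_pos)
  coords <- array(NA_real_, c(1, nrow(xyz), 3))
  coords[1, , ] <- xyz
  frames <- structure(list(coords = coords, forces = NULL, pe = NULL,
                           ke = NULL, box = matrix(1e3, 1, 3),
                           n_frames = 1L, n_atoms = nrow(xyz),
                           temperature = 298),
                      class = "mcc_frames")
  list(topology = list(atoms = atoms, bonds = bonds), frames = frames,
       hierarchy = build_hierarchy(list(atoms = atoms, bonds = bonds)))
}

# An in-memory FrameBatch from explicit arrays (bypasses file I/O where a
# test needs full control of every number).
frames_from_arrays <- function(coords, forces = NULL, pe = NULL, ke = NULL,
                               box = rep(1e3, 3), temperature = 298) {
  structure(list(coords = coords, forces = forces, pe = pe, ke = ke,
                 box = matrix(box, dim(coords)[1], 3, byrow = TRUE),
                 n_frames = dim(coords)[1], n_atoms = dim(coords)[2],
                 temperature = temperature),
            class = "mcc_frames")
}
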