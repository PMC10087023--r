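# Seeded synthetic fixtures with analytic or planted ground truth:
# Boltzmann-sampled harmonic systems (oracle for the covariance -> spectrum
# -> QHO chain), idealized water boxes (oracle for RAD shells and H-bond
# statistics), and a toy alanine dipeptide with planted dihedral conformers
# (oracle for the conformational entropy). Every generator writes its
# trajectory through the package's dump/TSV writers and re-reads it with
# load_frames(), so fixtures exercise the same I/O path as engine output.

# k (kJ/mol/A^2) over m (amu) -> SI rad^2/s^2 per molecule
.K_OVER_M_SI <- 1e3 / (mcc_constants$NA_ * 1e-20 * mcc_constants$amu)

# analytic QHO frequency of a 1-dof harmonic well
harmonic_freq <- function(k, mass) {
  sqrt((k / mass) * .K_OVER_M_SI) / (2 * pi)
}

#' Boltzmann-sampled harmonic system
#'
#' Independent 1-D harmonic wells (3 per atom): positions are Gaussian with
#' variance `kB T / k`, forces are `-k x`, per-atom energies are the exact
#' potential `k x^2 / 2` plus Boltzmann-sampled kinetic energies. The
#' analytic quantum-harmonic-oscillator entropy of the well set is attached
#' as metadata.
#'
#' @param k Spring constants per degree of freedom, kJ/mol/A^2; length must
#'   be a multiple of 3 (3 dofs per atom).
#' @param masses Mass per atom, amu (recycled).
#' @param temperature Temperature in K.
#' @param n_samples Number of frames.
#' @param seed RNG seed; the batch is bit-reproducible given the seed.
#' @param dir Directory for the round-tripped dump/TSV files (default a
#'   fresh temporary directory).
#' @return List with `frames` (an `mcc_frames`), `topology`, `k`, `masses`,
#'   `freq_analytic` (s^-1 per dof) and `S_analytic` (J/K/mol).
#' @export
sample_harmonic <- function(k, masses = 12, temperature = 298,
                            n_samples = 1000, seed = 1,
                            dir = tempfile("harm")) {
  stopifnot(length(k) %% 3 == 0, all(k > 0))
  n_atoms <- length(k) / 3
  masses <- rep_len(masses, n_atoms)
  set.seed(seed)
  kBT <- .kBT_kJ(temperature)
  K <- matrix(k, n_atoms, 3, byrow = TRUE)
  box <- rep(1e4, 3)
  coords <- array(NA_real_, c(n_samples, n_atoms, 3))
  forces <- array(NA_real_, c(n_samples, n_atoms, 3))
  pe <- ke <- matrix(NA_real_, n_samples, n_atoms)
  center <- box[1] / 2
  for (f in seq_len(n_samples)) {
    x <- matrix(stats::rnorm(3 * n_atoms, sd = sqrt(kBT / k)),
                n_atoms, 3, byrow = TRUE)
    coords[f, , ] <- x + center
    forces[f, , ] <- -K * x
    pe[f, ] <- rowSums(K * x^2) / 2
    ke[f, ] <- kBT / 2 * stats::rchisq(n_atoms, df = 3)
  }
  topo <- list(
    atoms = data.frame(index = seq_len(n_atoms),
                       name = paste0("P", seq_len(n_atoms)), element = "C",
                       resid = seq_len(n_atoms), resname = "PRT",
                       molid = seq_len(n_atoms), mass = masses, charge = 0,
                       stringsAsFactors = FALSE),
    bonds = matrix(integer(0), 0, 2, dimnames = list(NULL, c("i", "j"))))
  frames <- roundtrip_frames(dir, coords, forces, pe, ke, box, temperature)
  m_dof <- rep(masses, each = 3)
  nu <- harmonic_freq(k, m_dof)
  list(frames = frames, topology = topo, k = k, masses = masses,
       freq_analytic = nu,
       S_analytic = as.numeric(qho_entropy(nu, temperature)))
}

#' Idealized liquid-water box
#'
#' TIP3P-charged waters on a jittered cubic lattice at the requested number
#' density, with a freshly randomized rigid-water orientation every frame
#' (so donate and accept statistics are symmetric by construction). Forces
#' are isotropic Gaussian placeholders; per-atom energies are constants plus
#' noise. The unjittered oxygen lattice sites are recorded for brute-force
#' neighbor oracles.
#'
#' @param n_waters Number of waters (a perfect cube gives a full lattice).
#' @param n_frames Number of frames.
#' @param density Number density in waters/A^3 (default 0.0334, liquid
#'   water at ambient conditions).
#' @param jitter Gaussian lattice displacement, A (default 0.3).
#' @param temperature Temperature in K.
#' @param seed RNG seed.
#' @param dir Round-trip directory.
#' @return List with `frames`, `topology`, `hierarchy`, `box`, `o_sites`
#'   (unjittered lattice sites), `pe_per_atom`, `ke_per_atom`.
#' @export
make_water_box_frames <- function(n_waters = 216, n_frames = 5,
                                  density = 0.0334, jitter = 0.3,
                                  temperature = 298, seed = 1,
                                  dir = tempfile("wbox")) {
  stopifnot(n_waters >= 2)
  set.seed(seed)
  L <- (n_waters / density)^(1 / 3)
  m <- ceiling(n_waters^(1 / 3))
  grid <- as.matrix(expand.grid(x = seq_len(m), y = seq_len(m),
                                z = seq_len(m)))[seq_len(n_waters), ]
  o_sites <- (grid - 0.5) * (L / m)
  topo <- water_topology(n_waters)
  n_atoms <- 3 * n_waters
  coords <- array(NA_real_, c(n_frames, n_atoms, 3))
  forces <- array(stats::rnorm(n_frames * n_atoms * 3, sd = 20),
                  c(n_frames, n_atoms, 3))
  pe <- matrix(-41 + stats::rnorm(n_frames * n_atoms, sd = 0.5),
               n_frames, n_atoms)
  ke <- matrix(3.72 + stats::rnorm(n_frames * n_atoms, sd = 0.2),
               n_frames, n_atoms)
  r_oh <- 0.9572; half <- 104.52 / 2 * pi / 180
  for (f in seq_len(n_frames)) {
    o <- o_sites + matrix(stats::rnorm(3 * n_waters, sd = jitter),
                          n_waters, 3)
    o <- o %% L
    for (w in seq_len(n_waters)) {
      # random rigid orientation
      q <- stats::rnorm(4); q <- q / vec_norm(q)
      Rm <- quat_rot(q)
      h1 <- Rm %*% (r_oh * c(cos(half), sin(half), 0))
      h2 <- Rm %*% (r_oh * c(cos(half), -sin(half), 0))
      i0 <- 3 * (w - 1)
      coords[f, i0 + 1, ] <- o[w, ]
      coords[f, i0 + 2, ] <- o[w, ] + as.numeric(h1)
      coords[f, i0 + 3, ] <- o[w, ] + as.numeric(h2)
    }
  }
  frames <- roundtrip_frames(dir, coords, forces, pe, ke, rep(L, 3),
                             temperature)
  list(frames = frames, topology = topo, hierarchy = build_hierarchy(topo),
       box = rep(L, 3), o_sites = o_sites)
}

# unit quaternion -> rotation matrix
quat_rot <- function(q) {
  w <- q[1]; x <- q[2]; y <- q[3]; z <- q[4]
  matrix(c(1 - 2 * (y^2 + z^2), 2 * (x * y - w * z), 2 * (x * z + w * y),
           2 * (x * y + w * z), 1 - 2 * (x^2 + z^2), 2 * (y * z - w * x),
           2 * (x * z - w * y), 2 * (y * z + w * x), 1 - 2 * (x^2 + y^2)),
         3, 3, byrow = TRUE)
}

water_topology <- function(n_waters, l0 = 0L) {
  at <- data.frame(
    index = seq_len(3 * n_waters),
    name = rep(c("O", "H1", "H2"), n_waters),
    element = rep(c("O", "H", "H"), n_waters),
    resid = rep(seq_len(n_waters), each = 3) + l0,
    resname = "WAT",
    molid = rep(seq_len(n_waters), each = 3) + l0,
    mass = rep(c(15.9994, 1.008, 1.008), n_waters),
    charge = rep(c(-0.834, 0.417, 0.417), n_waters),
    stringsAsFactors = FALSE)
  o <- 3 * (seq_len(n_waters) - 1) + 1
  bonds <- cbind(i = c(o, o), j = c(o + 1, o + 2))
  storage.mode(bonds) <- "integer"
  list(atoms = at, bonds = bonds[order(bonds[, 1]), , drop = FALSE])
}

#' Toy alanine dipeptide with planted backbone conformers
#'
#' Builds an idealized ACE-ALA-NME geometry (22 atoms, 10 united atoms) and
#' generates frames in which the backbone phi dihedral C-N-CA-C follows a
#' planted conformer plan: per frame a state is drawn from `plan$p` and the
#' angle from a wrapped normal around `plan$centers[state]` with sd
#' `plan$sigma` degrees. All atoms on the C-side of the N-CA bond co-rotate
#' rigidly. The exact state sequence and the analytic Shannon entropy of the
#' plan are attached.
#'
#' @param n_frames Number of frames.
#' @param plan List with `p` (state probabilities), `centers` (degrees) and
#'   `sigma` (degrees, default 10).
#' @param temperature Temperature in K.
#' @param seed RNG seed.
#' @param force_sd Gaussian placeholder force scale, kJ/mol/A.
#' @param dir Round-trip directory.
#' @return List with `frames`, `topology`, `hierarchy`, `labels` (planted
#'   per-frame state), `angles` (planted phi in degrees), `phi_atoms` (the
#'   C-N-CA-C atom ids), `S_topo_analytic` (J/K/mol).
#' @export
make_toy_dipeptide <- function(n_frames = 1000,
                               plan = list(p = c(0.5, 0.3, 0.2),
                                           centers = c(-60, 60, 180),
                                           sigma = 10),
                               temperature = 298, seed = 1, force_sd = 30,
                               dir = tempfile("dipep")) {
  set.seed(seed)
  base <- dipeptide_geometry()
  topo <- base$topology
  n_atoms <- nrow(topo$atoms)
  phi_atoms <- base$phi_atoms          # C(ACE), N, CA, C(ALA)
  rot_set <- base$phi_rotating         # atoms rigidly following the dihedral
  phi0 <- dihedral_angle(base$xyz[phi_atoms[1], ], base$xyz[phi_atoms[2], ],
                         base$xyz[phi_atoms[3], ], base$xyz[phi_atoms[4], ])
  labels <- sample.int(length(plan$p), n_frames, replace = TRUE,
                       prob = plan$p)
  sigma <- plan$sigma %||% 10
  angles <- wrap180(plan$centers[labels] + stats::rnorm(n_frames, sd = sigma))
  box <- rep(100, 3)
  coords <- array(NA_real_, c(n_frames, n_atoms, 3))
  axis_a <- base$xyz[phi_atoms[2], ]; axis_b <- base$xyz[phi_atoms[3], ]
  for (f in seq_len(n_frames)) {
    Rm <- rotation_about_axis(axis_b - axis_a,
                              (angles[f] - phi0) * pi / 180)
    x <- base$xyz
    x[rot_set, ] <- sweep(sweep(x[rot_set, , drop = FALSE], 2, axis_b) %*%
                            t(Rm), 2, axis_b, "+")
    coords[f, , ] <- x + box[1] / 2
  }
  forces <- array(stats::rnorm(n_frames * n_atoms * 3, sd = force_sd),
                  c(n_frames, n_atoms, 3))
  pe <- matrix(-50 + stats::rnorm(n_frames * n_atoms, sd = 1),
               n_frames, n_atoms)
  ke <- matrix(3.72 + stats::rnorm(n_frames * n_atoms, sd = 0.2),
               n_frames, n_atoms)
  frames <- roundtrip_frames(dir, coords, forces, pe, ke, box, temperature)
  p <- plan$p / sum(plan$p)
  list(frames = frames, topology = topo, hierarchy = build_hierarchy(topo),
       labels = labels, angles = angles, phi_atoms = phi_atoms,
       S_topo_analytic = -mcc_constants$R * sum(p * log(p)))
}

#' Toy solvated dipeptide
#'
#' The dipeptide of [make_toy_dipeptide()] centered in a jittered water
#' lattice, waters overlapping the solute removed. Exercises RAD shells,
#' proximity grouping, hydrogen bonds, and the full free-energy pipeline at
#' desk scale.
#'
#' @param n_frames Number of frames.
#' @param n_waters Waters before overlap removal.
#' @param seed RNG seed.
#' @param temperature Temperature in K.
#' @param dir Round-trip directory.
#' @return List with `frames`, `topology`, `hierarchy`, and `n_waters_kept`.
#' @export
make_solvated_dipeptide <- function(n_frames = 3, n_waters = 125, seed = 1,
                                    temperature = 298,
                                    dir = tempfile("solv")) {
  set.seed(seed)
  pep <- dipeptide_geometry()
  wb <- make_water_box_frames(n_waters = n_waters, n_frames = n_frames,
                              seed = seed + 1)
  L <- wb$box[1]
  pep_xyz <- sweep(pep$xyz, 2, colMeans(pep$xyz))
  # drop waters whose lattice site is within 4 A of any solute heavy atom
  center <- rep(L / 2, 3)
  keep_w <- vapply(seq_len(nrow(wb$o_sites)), function(w) {
    all(mi_dist(wb$o_sites[w, ] - center, pep_xyz, rep(L, 3)) > 4)
  }, TRUE)
  kept <- which(keep_w)
  n_at_pep <- nrow(pep$topology$atoms)
  wtopo <- water_topology(length(kept), l0 = max(pep$topology$atoms$molid))
  wtopo$atoms$index <- wtopo$atoms$index + n_at_pep
  wtopo$bonds <- wtopo$bonds + n_at_pep
  topo <- list(atoms = rbind(pep$topology$atoms,
                             stats::setNames(wtopo$atoms,
                                             names(pep$topology$atoms))),
               bonds = rbind(pep$topology$bonds, wtopo$bonds))
  topo$atoms$index <- seq_len(nrow(topo$atoms))
  w_atom_idx <- as.vector(vapply(kept, function(w)
    (3 * (w - 1) + 1):(3 * w), integer(3)))
  n_atoms <- nrow(topo$atoms)
  coords <- array(NA_real_, c(n_frames, n_atoms, 3))
  for (f in seq_len(n_frames)) {
    coords[f, seq_len(n_at_pep), ] <- sweep(pep_xyz, 2, center, "+")
    coords[f, (n_at_pep + 1):n_atoms, ] <-
      wb$frames$coords[f, w_atom_idx, , drop = TRUE]
  }
  forces <- array(stats::rnorm(n_frames * n_atoms * 3, sd = 25),
                  c(n_frames, n_atoms, 3))
  pe <- matrix(-45 + stats::rnorm(n_frames * n_atoms, sd = 1),
               n_frames, n_atoms)
  ke <- matrix(3.72 + stats::rnorm(n_frames * n_atoms, sd = 0.2),
               n_frames, n_atoms)
  frames <- roundtrip_frames(dir, coords, forces, pe, ke, rep(L, 3),
                             temperature)
  list(frames = frames, topology = topo, hierarchy = build_hierarchy(topo),
       n_waters_kept = length(kept), box = rep(L, 3))
}

# Write a generated batch through the package writers and re-read it, so
# every fixture exercises the dump/TSV I/O path.
roundtrip_frames <- function(dir, coords, forces, pe, ke, box, temperature) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  cpath <- file.path(dir, "coords.dump")
  fpath <- file.path(dir, "forces.dump")
  epath <- file.path(dir, "energies.tsv")
  write_lammps_dump(cpath, coords = coords, box = box)
  write_lammps_dump(fpath, forces = forces, box = box)
  write_energy_tsv(epath, pe, ke)
  load_frames(cpath, forces = fpath, energies = epath,
              temperature = temperature)
}

#' Write a topology in the package TSV dialect
#'
#' @param topology A topology list.
#' @param atoms_path,bonds_path Output paths.
#' @return `atoms_path`, invisibly.
#' @export
write_topology_tsv <- function(topology, atoms_path, bonds_path) {
  write_tsv_file(topology$atoms, atoms_path)
  write_tsv_file(as.data.frame(topology$bonds), bonds_path)
  invisible(atoms_path)
}

# Idealized ACE-ALA-NME geometry built from internal coordinates.
dipeptide_geometry <- function() {
  at <- function(i) xyz[i, ]
  xyz <- matrix(NA_real_, 22, 3)
  # heavy-atom skeleton: CH3(2)-C(5)-N(7)-CA(9)[-CB(11)]-C(15)-N(17)-CH3(19)
  xyz[2, ] <- c(0, 0, 0)
  xyz[5, ] <- c(1.52, 0, 0)
  xyz[7, ] <- xyz[5, ] + 1.33 * c(cos(pi / 3), sin(pi / 3), 0)
  xyz[9, ] <- nerf(at(2), at(5), at(7), 1.46, 121, 180)
  xyz[11, ] <- nerf(at(5), at(7), at(9), 1.53, 110, -122)
  xyz[15, ] <- nerf(at(5), at(7), at(9), 1.52, 110, -60)   # phi = -60
  xyz[6, ] <- nerf(at(9), at(7), at(5), 1.23, 122, 180)
  xyz[16, ] <- nerf(at(7), at(9), at(15), 1.23, 121, 135)
  xyz[17, ] <- nerf(at(7), at(9), at(15), 1.33, 116, -45)  # psi = -45
  xyz[19, ] <- nerf(at(9), at(15), at(17), 1.46, 122, 180)
  # hydrogens
  xyz[1, ] <- nerf(at(7), at(5), at(2), 1.09, 109.5, 60)
  xyz[3, ] <- nerf(at(7), at(5), at(2), 1.09, 109.5, 180)
  xyz[4, ] <- nerf(at(7), at(5), at(2), 1.09, 109.5, 300)
  xyz[8, ] <- nerf(at(2), at(5), at(7), 1.01, 119, 180)
  xyz[10, ] <- nerf(at(5), at(7), at(9), 1.09, 109, 60)
  xyz[12, ] <- nerf(at(7), at(9), at(11), 1.09, 109.5, 60)
  xyz[13, ] <- nerf(at(7), at(9), at(11), 1.09, 109.5, 180)
  xyz[14, ] <- nerf(at(7), at(9), at(11), 1.09, 109.5, 300)
  xyz[18, ] <- nerf(at(9), at(15), at(17), 1.01, 119, 0)
  xyz[20, ] <- nerf(at(15), at(17), at(19), 1.09, 109.5, 60)
  xyz[21, ] <- nerf(at(15), at(17), at(19), 1.09, 109.5, 180)
  xyz[22, ] <- nerf(at(15), at(17), at(19), 1.09, 109.5, 300)
  names_ <- c("HH31", "CH3", "HH32", "HH33", "C", "O",
              "N", "H", "CA", "HA", "CB", "HB1", "HB2", "HB3", "C", "O",
              "N", "H", "CH3", "HH31", "HH32", "HH33")
  elem <- c("H", "C", "H", "H", "C", "O",
            "N", "H", "C", "H", "C", "H", "H", "H", "C", "O",
            "N", "H", "C", "H", "H", "H")
  mass <- c(H = 1.008, C = 12.011, N = 14.007, O = 15.9994)[elem]
  chg <- c(0.1123, -0.3662, 0.1123, 0.1123, 0.5972, -0.5679,
           -0.4157, 0.2719, 0.0337, 0.0823, -0.1825, 0.0603, 0.0603,
           0.0603, 0.5973, -0.5679,
           -0.4157, 0.2719, -0.149, 0.0976, 0.0976, 0.0976)
  resid <- c(rep(1L, 6), rep(2L, 10), rep(3L, 6))
  resname <- c(rep("ACE", 6), rep("ALA", 10), rep("NME", 6))
  bonds <- matrix(c(2, 1, 2, 3, 2, 4, 2, 5, 5, 6, 5, 7, 7, 8, 7, 9, 9, 10,
                    9, 11, 11, 12, 11, 13, 11, 14, 9, 15, 15, 16, 15, 17,
                    17, 18, 17, 19, 19, 20, 19, 21, 19, 22),
                  ncol = 2, byrow = TRUE, dimnames = list(NULL, c("i", "j")))
  storage.mode(bonds) <- "integer"
  topo <- list(atoms = data.frame(index = 1:22, name = names_,
                                  element = elem, resid = resid,
                                  resname = resname, molid = 1L,
                                  mass = unname(mass), charge = chg,
                                  stringsAsFactors = FALSE),
               bonds = bonds)
  # atoms rigidly following the phi dihedral (C-side of the N-CA bond)
  list(topology = topo, xyz = xyz, phi_atoms = c(5L, 7L, 9L, 15L),
       phi_rotating = 10:22)
}

# NeRF internal-coordinate placement: position of d bonded to c, with bond
# length r, angle b-c-d theta (deg) and dihedral a-b-c-d phi (deg).
nerf <- function(a, b, c_, r, theta, phi) {
  theta <- theta * pi / 180; phi <- phi * pi / 180
  bc <- unit_vec(c_ - b)
  n <- unit_vec(cross3(b - a, bc))
  M <- cbind(bc, cross3(n, bc), n)
  d2 <- r * c(-cos(theta), sin(theta) * cos(phi), sin(theta) * sin(phi))
  as.numeric(c_ + M %*% d2)
}
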