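# Local frames, force/torque covariances, spectra and QHO entropy.

test_that("residue backbone frame matches hand geometry", {
  xyz <- rbind(c(0, 0, 0),    # N
               c(1, 0, 0),    # CA
               c(1, 1, 0))    # C
  fr <- residue_frame(xyz, bb = c(1, 2, 3))
  expect_equal(fr$origin, c(2 / 3, 1 / 3, 0))
  expect_equal(fr$axes[1, ], c(1, 1, 0) / sqrt(2))       # N -> C
  expect_equal(abs(fr$axes[2, ]), c(0, 0, 1))            # plane normal
  expect_equal(abs(sum(fr$axes[3, ] * c(1, -1, 0) / sqrt(2))), 1)
  # orthonormal right-handed to tight tolerance
  expect_equal(fr$axes %*% t(fr$axes), diag(3), tolerance = 1e-10)
  expect_equal(det(fr$axes), 1, tolerance = 1e-10)
})

test_that("point UA frame is the identity at the heavy atom", {
  xyz <- rbind(c(2, 3, 4))
  fr <- ua_frame(xyz, heavy = 1, hydrogens = integer(0))
  expect_equal(fr$origin, c(2, 3, 4))
  expect_equal(fr$axes, diag(3))
})

test_that("water principal axes diagonalize the inertia tensor", {
  # symmetric planar water: axes along symmetry axis, in-plane, normal
  xyz <- rbind(c(0, 0, 0), c(0.76, 0.59, 0), c(-0.76, 0.59, 0))
  m <- c(15.9994, 1.008, 1.008)
  fr <- principal_frame(xyz, m)
  r <- sweep(xyz, 2, fr$origin) %*% t(fr$axes)
  I <- diag(3) * sum(m * rowSums(r^2)) - t(r) %*% (r * m)
  expect_equal(I[lower.tri(I)], rep(0, 3), tolerance = 1e-10)
  # one axis is the out-of-plane normal
  expect_true(any(abs(abs(fr$axes %*% c(0, 0, 1)) - 1) < 1e-10))
})

test_that("zero forces give a zero covariance matrix", {
  coords <- array(rep(c(0, 0, 0, 2, 0, 0), each = 4), c(4, 2, 3))
  forces <- array(0, c(4, 2, 3))
  topo <- list(atoms = data.frame(index = 1:2, name = c("P1", "P2"),
                                  element = "C", resid = 1:2, resname = "PRT",
                                  molid = 1L, mass = 12, charge = 0,
                                  stringsAsFactors = FALSE),
               bonds = matrix(integer(0), 0, 2))
  h <- build_hierarchy(topo)
  fb <- frames_from_arrays(coords, forces)
  acc <- suppressWarnings(accumulate_covariance(fb, h, "polymer"))
  expect_equal(acc$fcov, matrix(0, 3, 3))
})

test_that("Boltzmann-sampled trap reproduces equipartition force variances", {
  k <- c(150, 150, 150)
  n <- 2e4
  hs <- sample_harmonic(k = k, masses = 18, n_samples = n, seed = 31)
  h <- build_hierarchy(hs$topology)
  acc <- accumulate_covariance(hs$frames, h, "polymer", polymer = 1)
  kBT <- 8.31446261815324 * 298 / 1000
  lam_expect <- k[1] * kBT / 18   # <F^2>/m per axis
  # eigenvalues within ~4 relative standard errors (SE ~ sqrt(2/n))
  tol <- 4 * sqrt(2 / n) * lam_expect
  expect_true(all(abs(diag(acc$fcov) - lam_expect) < tol))
})

test_that("independent units decorrelate as sampling grows", {
  set.seed(77)
  n <- 5000
  # two independent 1-atom monomers in one molecule
  topo <- list(atoms = data.frame(index = 1:2, name = c("P1", "P2"),
                                  element = "C", resid = 1:2, resname = "PRT",
                                  molid = 1L, mass = 12, charge = 0,
                                  stringsAsFactors = FALSE),
               bonds = matrix(integer(0), 0, 2))
  h <- build_hierarchy(topo)
  coords <- array(rep(c(0, 0, 0, 5, 0, 0), each = n), c(n, 2, 3))
  forces <- array(rnorm(n * 6), c(n, 2, 3))
  fb <- frames_from_arrays(coords, forces)
  acc <- accumulate_covariance(fb, h, "monomer", polymer = 1)
  off <- acc$fcov[1:3, 4:6]
  expect_true(all(abs(off) < 6 / sqrt(n)))   # ~0 at the sampling noise scale
  expect_true(all(abs(diag(acc$fcov) - 1 / 12) < 6 / sqrt(n)))
})

test_that("the analytic harmonic identity survives the spectrum conversion", {
  # feed an exact trap covariance: lambda = k kB T / m -> nu = sqrt(k/m)/2pi
  k <- c(80, 200, 640); m <- 16; Tk <- 298
  kBT <- 8.31446261815324 * Tk / 1000
  acc <- structure(list(level = "polymer", unit_ids = 1L,
                        fcov = diag(k * kBT / m),
                        tcov = matrix(0, 0, 0), rot_units = integer(0),
                        n_units = 1L, n_samples = Inf),
                   class = "mcc_covacc")
  sp <- spectrum_from_covariance(acc, Tk)
  nu_expect <- sqrt((k / m) * 1e26) / (2 * pi)
  expect_equal(sort(sp$freq_trans), sort(nu_expect), tolerance = 1e-9)
})

test_that("mode bookkeeping: kept + removed + clamped equals matrix dimension", {
  set.seed(12)
  n <- 50
  topo <- list(atoms = data.frame(index = 1:4, name = paste0("P", 1:4),
                                  element = "C", resid = 1:4, resname = "PRT",
                                  molid = 1L, mass = 12, charge = 0,
                                  stringsAsFactors = FALSE),
               bonds = matrix(integer(0), 0, 2))
  h <- build_hierarchy(topo)
  coords <- array(rep(runif(12, 0, 5), each = n), c(n, 4, 3))
  forces <- array(rnorm(n * 12), c(n, 4, 3))
  fb <- frames_from_arrays(coords, forces)
  acc <- accumulate_covariance(fb, h, "monomer", polymer = 1)
  sp <- spectrum_from_covariance(acc, 298)
  expect_equal(length(sp$freq_trans) + length(sp$freq_rot) +
                 sp$n_removed + sp$n_clamped, nrow(acc$fcov))
  # sub-polymer level: exactly 6 smallest force eigenvalues removed
  expect_equal(sp$n_removed, 6L)
})

test_that("zero and extreme frequencies behave at the QHO limits", {
  Tk <- 298
  expect_equal(as.numeric(qho_entropy(0, Tk)), 0)          # dropped mode
  expect_lt(qho_entropy(1e16, Tk), 1e-8)                   # frozen mode
  # classical limit: S -> R (1 - log x) as x -> 0
  x <- 1e-6
  nu <- freq_for_x(x, Tk)
  expect_equal(as.numeric(qho_entropy(nu, Tk)),
               8.31446261815324 * (1 - log(x)), tolerance = 1e-5)
})

test_that("temperature must be positive", {
  expect_error(qho_entropy(1e12, -5), "positive")
  acc <- structure(list(level = "polymer", fcov = diag(3),
                        tcov = matrix(0, 0, 0)), class = "mcc_covacc")
  expect_error(spectrum_from_covariance(acc, 0), "positive")
})

test_that("stiffer traps have lower vibrational entropy", {
  Tk <- 298
  s <- vapply(c(50, 100, 400, 1600), function(k)
    as.numeric(qho_entropy(eemcc:::harmonic_freq(k, 12), Tk)), 0)
  expect_true(all(diff(s) < 0))
})

test_that("entropies are invariant under a rigid rotation of the system", {
  dp <- make_toy_dipeptide(n_frames = 40, seed = 21)
  h <- dp$hierarchy
  set.seed(3)
  q <- rnorm(4); q <- q / sqrt(sum(q^2))
  Rm <- eemcc:::quat_rot(q)
  rot <- dp$frames
  for (f in seq_len(rot$n_frames)) {
    rot$coords[f, , ] <- matrix(dp$frames$coords[f, , ], ncol = 3) %*% t(Rm)
    rot$forces[f, , ] <- matrix(dp$frames$forces[f, , ], ncol = 3) %*% t(Rm)
  }
  for (lvl in list(list(level = "polymer", polymer = 1),
                   list(level = "monomer", polymer = 1),
                   list(level = "ua", monomer = 2))) {
    a <- suppressWarnings(do.call(vibrational_entropy,
           c(list(dp$frames, h), lvl)))
    b <- suppressWarnings(do.call(vibrational_entropy,
           c(list(rot, h), lvl)))
    expect_equal(a$S_total, b$S_total, tolerance = 1e-8)
    expect_equal(a$S_trans, b$S_trans, tolerance = 1e-8)
    expect_equal(a$S_rot, b$S_rot, tolerance = 1e-8)
  }
})

test_that("protein entropy assembles additively over levels", {
  dp <- make_toy_dipeptide(n_frames = 60, seed = 8)
  h <- dp$hierarchy
  vp <- suppressWarnings(vibrational_entropy(dp$frames, h, "polymer",
                                             polymer = 1))
  vm <- suppressWarnings(vibrational_entropy(dp$frames, h, "monomer",
                                             polymer = 1))
  s_ua <- sum(vapply(h$monomers$id, function(m)
    suppressWarnings(vibrational_entropy(dp$frames, h, "ua",
                                         monomer = m))$S_total, 0))
  conf <- conformational_entropy(dp$frames, h)
  total <- vp$S_total + vm$S_total + s_ua + sum(conf$S_topo)
  # the ledger total is exactly the sum of its parts
  expect_equal(total,
               vp$S_trans + vp$S_rot + vm$S_trans + vm$S_rot + s_ua +
                 sum(conf$S_topo))
  expect_true(is.finite(total) && total > 0)
})
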