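# Feature covariance, baseline referencing, neighbor matrices,
# hydrophobicity ranking, secondary-structure grouping, RMSD.

test_that("standardized covariance hits the exact reference values", {
  X <- data.frame(a = c(1, 2, 3), b = c(1, 3, 2))
  cv <- feature_covariance(X)
  expect_equal(cv["a", "b"], 0.5)            # the 3-point example, exactly
  expect_equal(cv["a", "a"], 1)
  cv2 <- feature_covariance(data.frame(x = 1:5, y = 1:5))
  expect_equal(cv2["x", "y"], 1)
  cv3 <- feature_covariance(data.frame(x = 1:5, y = -(1:5)))
  expect_equal(cv3["x", "y"], -1)
})

test_that("covariance matrices are symmetric with unit diagonal and bounded entries", {
  set.seed(3)
  X <- matrix(rnorm(40), 10, 4, dimnames = list(NULL, letters[1:4]))
  cv <- feature_covariance(X)
  expect_equal(cv, t(cv))
  expect_equal(unname(diag(cv)), rep(1, 4))
  expect_true(all(cv >= -1 - 1e-12 & cv <= 1 + 1e-12))
})

test_that("constant feature columns are dropped with a warning", {
  X <- data.frame(a = c(1, 2, 3), b = c(5, 5, 5))
  expect_warning(cv <- feature_covariance(X), "constant")
  expect_equal(colnames(cv), "a")
})

test_that("baseline referencing subtracts per type and skips terminals", {
  res <- data.frame(monomer = 1:5, resname = c("ACE", "ALA", "GLY", "ALA",
                                               "NME"),
                    polymer = 1, H = c(-10, -108, -90, -104, -12),
                    S = c(10, 90, 80, 95, 12), stringsAsFactors = FALSE)
  base <- data.frame(resname = c("ALA", "GLY"), H = c(-100, -88),
                     S = c(100, 84), stringsAsFactors = FALSE)
  d <- referenced_deltas(res, base, temperature = 298)
  expect_equal(nrow(d), 3)            # terminals (ACE, NME rows) excluded
  expect_equal(d$dH[d$monomer == 2], -8)
  expect_equal(d$dS[d$monomer == 3], -4)
  expect_equal(d$dG, d$dH - 298 * d$dS / 1000)
  # a residue identical to its baseline has all deltas zero
  res0 <- res; res0$H[2] <- -100; res0$S[2] <- 100
  d0 <- referenced_deltas(res0, base, temperature = 298)
  expect_equal(d0$dH[d0$monomer == 2], 0)
  expect_equal(d0$dG[d0$monomer == 2], 0)
})

test_that("referencing is affine: a common offset cancels", {
  res <- data.frame(monomer = 1:4, resname = c("X", "ALA", "GLY", "Y"),
                    polymer = 1, H = c(0, -50, -60, 0), S = c(0, 40, 40, 0),
                    stringsAsFactors = FALSE)
  base <- data.frame(resname = c("ALA", "GLY", "X", "Y"), H = c(-45, -55, 0, 0),
                     S = c(42, 41, 0, 0))
  d1 <- referenced_deltas(res, base, 298)
  res2 <- res; res2$H <- res2$H + 7
  base2 <- base; base2$H <- base2$H + 7
  d2 <- referenced_deltas(res2, base2, 298)
  expect_equal(d1$dH, d2$dH)
  expect_equal(d1$dG, d2$dG)
})

test_that("residues without a baseline type are skipped with a message", {
  res <- data.frame(monomer = 1:4, resname = c("X", "ALA", "ZZZ", "Y"),
                    polymer = 1, H = c(0, -50, -60, 0), S = c(0, 40, 40, 0),
                    stringsAsFactors = FALSE)
  base <- data.frame(resname = "ALA", H = -45, S = 42)
  expect_message(d <- referenced_deltas(res, base, 298), "ZZZ")
  expect_equal(d$resname, "ALA")
})

test_that("neighbor matrices index N- and C-side partners correctly", {
  # chain A-B: A contributes to (A | C-side B); B to (B | N-side A)
  deltas <- data.frame(monomer = 1:2, resname = c("A", "B"), polymer = 1,
                       dG = c(-1.5, 2.5), stringsAsFactors = FALSE)
  seqs <- list(`1` = setNames(c("A", "B"), 1:2))
  nm <- neighbor_effect_matrix(deltas, seqs)
  expect_equal(nm$C_side["A", "B"], -1.5)
  expect_equal(nm$N_side["B", "A"], 2.5)
  expect_equal(nm$counts_C["A", "B"], 1)
  expect_equal(nm$counts_N["B", "A"], 1)
  # never-observed pairs stay at count 0 with NA mean
  expect_equal(nm$counts_N["A", "B"], 0)
  expect_true(is.na(nm$N_side["A", "B"]))
})

test_that("a planted N-side signal is recovered in the matrix column", {
  # every residue following K is destabilized by exactly -2
  types <- c("K", "A", "G", "K", "G", "A", "K", "A")
  dg <- ifelse(c("", head(types, -1)) == "K", -2, 1)
  deltas <- data.frame(monomer = seq_along(types), resname = types,
                       polymer = 1, dG = dg, stringsAsFactors = FALSE)
  seqs <- list(`1` = setNames(types, seq_along(types)))
  nm <- neighbor_effect_matrix(deltas, seqs)
  expect_true(all(nm$N_side[c("A", "G"), "K"] == -2, na.rm = TRUE))
})

test_that("hydrophobicity ranks order by water free energy with alphabetical ties", {
  g <- c(ALA = -54, ASP = -56, GLY = -54, LYS = -55.2)
  hr <- hydrophobicity_rank(g)
  expect_equal(hr$resname, c("ASP", "LYS", "ALA", "GLY"))
  expect_equal(hr$HR, 1:4)
  # argsort oracle on a random vector
  set.seed(9)
  g2 <- setNames(round(rnorm(8), 3), paste0("R", 1:8))
  hr2 <- hydrophobicity_rank(g2)
  expect_equal(hr2$G_water, sort(g2), ignore_attr = TRUE)
})

test_that("secondary-structure grouping reproduces weighted means and percentages", {
  wt <- data.frame(nearest_monomer = c(1, 2, 3),
                   TS = c(20, 21, 22), H = c(-34, -33, -32),
                   G = c(-54, -54, -54), N = c(2, 6, 2))
  ss <- data.frame(monomer = 1:3, class = c("coil", "coil", "ahelix"),
                   stringsAsFactors = FALSE)
  out <- secondary_structure_grouping(wt, ss, all_residues = 1:3)
  coil <- out[out$class == "coil", ]
  expect_equal(coil$TS, (20 * 2 + 21 * 6) / 8)
  expect_equal(coil$pct_residues, 100 * 2 / 3)
  expect_equal(coil$pct_waters, 80)
  expect_equal(sum(out$pct_waters), 100, tolerance = 0.1)
  expect_equal(sum(out$pct_residues), 100, tolerance = 0.1)
  # empty classes are omitted
  expect_false("turn" %in% out$class)
  # one class takes everything when all residues share it
  out1 <- secondary_structure_grouping(wt, data.frame(monomer = 1:3,
                                                      class = "coil"),
                                       all_residues = 1:3)
  expect_equal(out1$pct_residues, 100)
  expect_equal(out1$pct_waters, 100)
})

test_that("unlabeled residues go to class 'other' with a message", {
  wt <- data.frame(nearest_monomer = c(1, 2), TS = c(20, 21),
                   H = c(-34, -33), G = c(-54, -54), N = c(1, 1))
  ss <- data.frame(monomer = 1, class = "coil", stringsAsFactors = FALSE)
  expect_message(out <- secondary_structure_grouping(wt, ss, 1:2), "other")
  expect_true("other" %in% out$class)
})

test_that("side-chain RMSD is zero against the first frame of a rigid trajectory", {
  dp <- make_toy_dipeptide(n_frames = 4,
                           plan = list(p = 1, centers = -60, sigma = 0),
                           seed = 2)
  rm <- residue_rmsd(make_whole(dp$frames, dp$hierarchy), dp$hierarchy)
  expect_equal(rm$rmsd[rm$monomer == 2], 0, tolerance = 1e-6)
})
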