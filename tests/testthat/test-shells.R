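# RAD coordination shells, topological hydrogen bonds, proximity grouping.

test_that("RAD blocking follows the angular inequality on canonical geometries", {
  # two particles: always mutual neighbors (no possible blocker)
  xyz <- rbind(c(0, 0, 0), c(3.1, 0.2, -1))
  expect_equal(rad_shell(xyz, 1)$ids, 2L)
  expect_equal(rad_shell(xyz, 2)$ids, 1L)
  # collinear farther particle is blocked: 1/4 > 1 * cos(0) is false
  xyz <- rbind(c(0, 0, 0), c(1, 0, 0), c(2, 0, 0))
  expect_equal(rad_shell(xyz, 1)$ids, 2L)
  # perpendicular particle is kept: 1/4 > 1 * cos(90) = 0 holds
  xyz <- rbind(c(0, 0, 0), c(1, 0, 0), c(0, 2, 0))
  expect_equal(rad_shell(xyz, 1)$ids, c(2L, 3L))
})

test_that("RAD shells equal brute-force enumeration on random small configurations", {
  set.seed(101)
  for (rep in 1:25) {
    n <- sample(3:10, 1)
    xyz <- matrix(runif(3 * n, 0, 6), n, 3)
    for (i in seq_len(n)) {
      expect_equal(rad_shell(xyz, i, cutoff = 50)$ids, brute_rad(xyz, i),
                   info = sprintf("rep %d center %d", rep, i))
    }
  }
})

test_that("the nearest neighbor is always in the shell", {
  set.seed(202)
  for (rep in 1:20) {
    n <- sample(4:12, 1)
    xyz <- matrix(runif(3 * n, 0, 8), n, 3)
    for (i in seq_len(n)) {
      r <- sqrt(rowSums(sweep(xyz, 2, xyz[i, ])^2)); r[i] <- Inf
      expect_true(which.min(r) %in% rad_shell(xyz, i, cutoff = 50)$ids)
    }
  }
})

test_that("coincident UA positions are rejected", {
  xyz <- rbind(c(0, 0, 0), c(0, 0, 0), c(1, 1, 1))
  expect_error(rad_shell(xyz, 1), "coincident")
})

test_that("RAD shells respect minimum-image distances", {
  # neighbor across the periodic boundary is closer than it looks
  xyz <- rbind(c(0.5, 5, 5), c(9.5, 5, 5), c(3.5, 5, 5))
  sh <- rad_shell(xyz, 1, box = rep(10, 3), cutoff = 4)
  expect_equal(sh$ids[1], 2L)  # 1 A away through the boundary
  expect_equal(unname(sh$dists[1]), 1, tolerance = 1e-12)
})

test_that("bulk-water shell sizes land in the physical band", {
  wb <- make_water_box_frames(n_waters = 216, n_frames = 2, seed = 5)
  sm <- rad_shells(wb$frames, wb$hierarchy, frame_idx = 1:2)
  nc <- mean(unlist(lapply(sm$shells, function(sf)
    lengths(lapply(sf, `[[`, "ids")))))
  expect_gt(nc, 4)
  expect_lt(nc, 7)
})

test_that("the hydrogen bond goes to the most negative qDqA/r^2 acceptor", {
  # H1 at 1 A from O along +x; two chlorides at 2.0 and 1.8 A from H1
  sys <- donor_acceptor_system(o = c(10, 10, 10), h1 = c(11, 10, 10),
                               h2 = c(9.74, 10.93, 10),
                               cl_pos = rbind(c(13, 10, 10),
                                              c(11, 11.8, 10)))
  sm <- rad_shells(sys$frames, sys$hierarchy)
  hb <- assign_hbonds(sys$frames, sys$hierarchy, sm)
  rec <- hb[hb$hydrogen == 2, ]
  expect_equal(nrow(rec), 1)          # at most one acceptor per hydrogen
  expect_equal(rec$acceptor_atom, 5)  # the closer chloride (1.8 A)
  # score arithmetic: q_D q_A / r^2
  expect_equal(rec$score, 0.417 * (-1) / 1.8^2, tolerance = 1e-9)
})

test_that("equal hydrogen-bond scores break to the lowest atom index", {
  sys <- donor_acceptor_system(o = c(10, 10, 10), h1 = c(11, 10, 10),
                               h2 = c(9.74, 10.93, 10),
                               cl_pos = rbind(c(11, 12, 10),
                                              c(11, 8, 10)))  # both at 2 A
  sm <- rad_shells(sys$frames, sys$hierarchy)
  hb <- assign_hbonds(sys$frames, sys$hierarchy, sm)
  expect_equal(hb$acceptor_atom[hb$hydrogen == 2], 4)
})

test_that("a water donates at most twice per frame", {
  wb <- make_water_box_frames(n_waters = 27, n_frames = 2, seed = 9)
  sm <- rad_shells(wb$frames, wb$hierarchy)
  hb <- assign_hbonds(wb$frames, wb$hierarchy, sm)
  don_per_water <- table(hb$frame, hb$donor_ua)
  expect_true(all(don_per_water <= 2))
})

test_that("proximity grouping matches a brute-force nearest-distance scan", {
  sv <- make_solvated_dipeptide(n_frames = 2, n_waters = 64, seed = 4)
  h <- sv$hierarchy
  frames <- make_whole(sv$frames, h)
  sm <- rad_shells(frames, h)
  gr <- nearest_solute_grouping(frames, h, sm)
  heavy <- h$ua$heavy
  is_water_ua <- h$monomers$kind[h$ua$monomer] == "water"
  for (r in which(!is.na(gr$waters$nearest_monomer))) {
    f <- gr$waters$frame[r]
    w_ua <- gr$waters$water_ua[r]
    sh <- sm$shells[[match(f, sm$frames)]][[w_ua]]
    solute_in_shell <- sh$ids[!is_water_ua[sh$ids]]
    # oracle: nearest solute UA among shell members, by direct distance
    xyz <- matrix(frames$coords[f, heavy, ], ncol = 3)
    dd <- sqrt(rowSums(sweep(xyz[solute_in_shell, , drop = FALSE], 2,
                             xyz[w_ua, ])^2))
    expect_equal(gr$waters$nearest_ua[r], solute_in_shell[which.min(dd)])
    # the nearest residue contains the nearest UA
    expect_equal(gr$waters$nearest_monomer[r],
                 h$ua$monomer[gr$waters$nearest_ua[r]])
  }
})

test_that("waters touching two residues emit the residue-pair label", {
  sv <- make_solvated_dipeptide(n_frames = 1, n_waters = 64, seed = 4)
  h <- sv$hierarchy
  frames <- make_whole(sv$frames, h)
  sm <- rad_shells(frames, h)
  gr <- nearest_solute_grouping(frames, h, sm)
  multi <- gr$waters[!is.na(gr$waters$second_monomer), ]
  expect_gt(nrow(multi), 0)
  for (r in seq_len(nrow(multi))) {
    pr <- gr$pairs[gr$pairs$water == multi$water[r] &
                     gr$pairs$frame == multi$frame[r], ]
    expect_true(nrow(pr) >= 1)
    expect_true(all(pr$res_i < pr$res_j))
    # the nearest residue participates in at least one pair
    expect_true(multi$nearest_monomer[r] %in% c(pr$res_i, pr$res_j))
  }
})

test_that("waters with no solute contact are labeled bulk", {
  wb <- make_water_box_frames(n_waters = 27, n_frames = 1, seed = 2)
  sm <- rad_shells(wb$frames, wb$hierarchy)
  gr <- nearest_solute_grouping(wb$frames, wb$hierarchy, sm)
  expect_true(all(is.na(gr$waters$nearest_monomer)))
  expect_equal(nrow(gr$pairs), 0)
})

test_that("per-residue water counts add up to the first-shell total", {
  sv <- make_solvated_dipeptide(n_frames = 2, n_waters = 64, seed = 8)
  h <- sv$hierarchy
  frames <- make_whole(sv$frames, h)
  sm <- rad_shells(frames, h)
  gr <- nearest_solute_grouping(frames, h, sm)
  gw <- gr$waters[!is.na(gr$waters$nearest_monomer), ]
  by_res <- table(gw$nearest_monomer)
  expect_equal(sum(by_res), nrow(gw))
})

test_that("blocker variants agree on equilibrated water", {
  wb <- make_water_box_frames(n_waters = 64, n_frames = 1, seed = 13)
  xyz <- matrix(wb$frames$coords[1, wb$hierarchy$ua$heavy, ], ncol = 3)
  bx <- wb$frames$box[1, ]
  for (i in seq_len(12)) {
    a <- rad_shell(xyz, i, box = bx, blockers = "all_closer")
    b <- rad_shell(xyz, i, box = bx, blockers = "accepted")
    expect_true(all(a$ids %in% b$ids))
  }
})
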