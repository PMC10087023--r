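# Orientational (topographical) entropy of water from coordination-shell
# composition and hydrogen-bond donate/accept statistics.
#
# For each coordination-shell class c (bulk, or nearest-residue identity)
# and each neighbor type n, the probability that a neighbor of type n is
# hydrogen-bonded in the correct orientation is
#   p_HBn = [p_Dn/(p_Dn+p_An)] * [p_An/(p_Dn+p_An)],
# the shell-average is p_HB^av = sum_n p_HBn N_n / N_c, the effective number
# of bondable neighbors is N_eff = sum_n p_HBn N_n / 0.25 (0.25 being the
# ideal value for two hydrogen bonds with probability 0.5 each to donate
# and accept), and
#   S_or = kB sum_c p_c ln( N_eff * pi^(3/2) * p_HB^av / sigma ),  sigma = 2.

WATER_SYMMETRY <- 2

#' Hydrogen-bond probability for one neighbor type
#'
#' `p_HBn = [p_D/(p_D+p_A)] * [p_A/(p_D+p_A)]`; equals 0.25 when donating
#' and accepting are equally likely, and 0 when either never happens. Both
#' zero returns 0 by convention.
#'
#' @param p_d,p_a Probabilities of donating to / accepting from the type.
#' @return The orientation probability, in `[0, 0.25]`.
#' @export
phb <- function(p_d, p_a) {
  tot <- p_d + p_a
  ifelse(tot > 0, (p_d / tot) * (p_a / tot), 0)
}

#' Shell-averaged hydrogen-bond probability
#'
#' Weighted average of `p_HBn` over neighbor types, weights `N_n / N_c`.
#'
#' @param p_hbn Per-type orientation probabilities.
#' @param n_n Per-type mean neighbor counts.
#' @return `p_HB^av`.
#' @export
phb_avg <- function(p_hbn, n_n) {
  nc <- sum(n_n)
  if (nc <= 0) stop("empty coordination shell (N_c = 0)")
  sum(p_hbn * n_n) / nc
}

#' Effective number of hydrogen-bondable neighbors
#'
#' `N_eff = sum_n p_HBn N_n / 0.25`. For a homogeneous shell with
#' `p_HBn = 0.25` this reduces to the shell size `N_c`.
#'
#' @param p_hbn Per-type orientation probabilities.
#' @param n_n Per-type mean neighbor counts.
#' @return `N_eff >= 0`.
#' @export
neff <- function(p_hbn, n_n) {
  sum(p_hbn * n_n) / 0.25
}

#' Orientational entropy over coordination-shell classes
#'
#' `S_or = kB sum_c p_c ln(N_eff pi^{3/2} p_HB^av / sigma)` with sigma = 2
#' (the symmetry number of water). Classes whose logarithm argument is at or
#' below 1 contribute zero (a one-orientation state has no entropy); the
#' number of clamped classes is reported as an attribute.
#'
#' @param n_eff Per-class effective neighbor counts.
#' @param p_hb_av Per-class average orientation probabilities.
#' @param p_c Class weights (fractions of water-frames; normalized).
#' @return Entropy in J/K/mol with attributes `per_class` and `n_clamped`.
#' @export
orientational_entropy <- function(n_eff, p_hb_av, p_c = 1) {
  stopifnot(length(n_eff) == length(p_hb_av))
  p_c <- rep_len(p_c, length(n_eff))
  p_c <- p_c / sum(p_c)
  arg <- n_eff * pi^1.5 * p_hb_av / WATER_SYMMETRY
  per <- ifelse(arg > 1, mcc_constants$R * log(arg), 0)
  out <- sum(p_c * per)
  attr(out, "per_class") <- per
  attr(out, "n_clamped") <- sum(arg <= 1 & p_c > 0)
  out
}

# Neighbor-type taxonomy around the protein surface: water in the protein
# first shell, water outside it, protein UA, ion.
neighbor_type_of_ua <- function(ua_ids, hierarchy, first_shell_waters) {
  mon <- hierarchy$monomers
  kind <- mon$kind[hierarchy$ua$monomer[ua_ids]]
  wmon <- hierarchy$ua$monomer[ua_ids]
  ifelse(kind == "water",
         ifelse(wmon %in% first_shell_waters, "water_first_shell",
                "water_outside"),
         ifelse(kind == "ion", "ion", "protein_ua"))
}

#' Accumulate donor/acceptor statistics per water class and neighbor type
#'
#' Classes are the waters' nearest-solute labels (bulk, or nearest residue
#' id); neighbor types are water-in-protein-first-shell, water-outside,
#' protein UA, and ion. Donation and acceptance counts are accumulated over
#' all frames and converted to probabilities per class; shell compositions
#' are averaged per water-frame.
#'
#' @param hierarchy An `mcc_hierarchy`.
#' @param shellmap An `mcc_shellmap`.
#' @param hbonds data.frame from [assign_hbonds()].
#' @param grouping Output of [nearest_solute_grouping()].
#' @return An object of class `mcc_dastats`: list with `stats` data.frame
#'   (`class`, `type`, `N_n`, `N_D`, `N_A`, `p_D`, `p_A`, `p_HB`) and
#'   `classes` data.frame (`class`, `p_c`, `N_c`, `n_water_frames`).
#' @export
water_orientation_stats <- function(hierarchy, shellmap, hbonds, grouping) {
  gw <- grouping$waters
  gw$class <- ifelse(is.na(gw$nearest_monomer), "bulk",
                     paste0("res", gw$nearest_monomer))
  first_shell <- unique(gw$water[!is.na(gw$nearest_monomer)])
  ua2mon <- hierarchy$ua$monomer
  # donor/acceptor water UA per hydrogen-bond record
  hb_frame_key <- paste(hbonds$frame, hbonds$donor_ua)
  rows <- list()
  for (r in seq_len(nrow(gw))) {
    f <- gw$frame[r]; w_ua <- gw$water_ua[r]
    k <- match(f, shellmap$frames)
    sh <- shellmap$shells[[k]][[w_ua]]
    if (length(sh$ids) == 0) next
    types <- neighbor_type_of_ua(sh$ids, hierarchy, first_shell)
    # shell composition
    comp <- table(types)
    # donations from this water's hydrogens, by acceptor type
    don <- hbonds[hbonds$frame == f & hbonds$donor_ua == w_ua, ]
    acc <- hbonds[hbonds$frame == f & hbonds$acceptor_ua == w_ua, ]
    don_t <- if (nrow(don) > 0)
      neighbor_type_of_ua(don$acceptor_ua, hierarchy, first_shell) else
      character(0)
    acc_t <- if (nrow(acc) > 0)
      neighbor_type_of_ua(acc$donor_ua, hierarchy, first_shell) else
      character(0)
    rows[[length(rows) + 1]] <- list(class = gw$class[r], comp = comp,
                                     don = don_t, acc = acc_t)
  }
  if (length(rows) == 0) stop("no water shells to accumulate")
  classes <- unique(vapply(rows, `[[`, "", "class"))
  types_all <- c("water_first_shell", "water_outside", "protein_ua", "ion")
  stats <- expand.grid(class = classes, type = types_all,
                       stringsAsFactors = FALSE)
  stats$N_n <- stats$N_D <- stats$N_A <- 0
  n_wf <- setNames(numeric(length(classes)), classes)
  for (row in rows) {
    cl <- row$class
    n_wf[cl] <- n_wf[cl] + 1
    for (tp in names(row$comp)) {
      i <- which(stats$class == cl & stats$type == tp)
      stats$N_n[i] <- stats$N_n[i] + row$comp[[tp]]
    }
    for (tp in row$don) {
      i <- which(stats$class == cl & stats$type == tp)
      stats$N_D[i] <- stats$N_D[i] + 1
    }
    for (tp in row$acc) {
      i <- which(stats$class == cl & stats$type == tp)
      stats$N_A[i] <- stats$N_A[i] + 1
    }
  }
  stats$N_n <- stats$N_n / n_wf[stats$class]
  for (cl in classes) {
    i <- stats$class == cl
    sd_ <- sum(stats$N_D[i]); sa <- sum(stats$N_A[i])
    stats$p_D[i] <- if (sd_ > 0) stats$N_D[i] / sd_ else 0
    stats$p_A[i] <- if (sa > 0) stats$N_A[i] / sa else 0
  }
  stats$p_HB <- phb(stats$p_D, stats$p_A)
  cl_df <- data.frame(class = classes,
                      p_c = as.numeric(n_wf[classes] / sum(n_wf)),
                      N_c = vapply(classes, function(cl)
                        sum(stats$N_n[stats$class == cl]), 0),
                      n_water_frames = as.numeric(n_wf[classes]),
                      stringsAsFactors = FALSE)
  structure(list(stats = stats, classes = cl_df), class = "mcc_dastats")
}

#' Orientational entropy from accumulated donor/acceptor statistics
#'
#' @param dastats An `mcc_dastats` from [water_orientation_stats()].
#' @return data.frame per class (`class`, `p_c`, `N_c`, `N_eff`, `p_HB_av`,
#'   `S_or`), with the class-weighted total entropy (J/K/mol) as attribute
#'   `S_or_total`.
#' @export
orientational_entropy_from_stats <- function(dastats) {
  cl <- dastats$classes
  st <- dastats$stats
  cl$N_eff <- cl$p_HB_av <- NA_real_
  for (i in seq_len(nrow(cl))) {
    s <- st[st$class == cl$class[i], ]
    cl$N_eff[i] <- neff(s$p_HB, s$N_n)
    cl$p_HB_av[i] <- phb_avg(s$p_HB, s$N_n)
  }
  s_tot <- orientational_entropy(cl$N_eff, cl$p_HB_av, cl$p_c)
  cl$S_or <- attr(s_tot, "per_class")
  attr(cl, "S_or_total") <- as.numeric(s_tot)
  cl
}
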