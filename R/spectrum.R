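# Eigenvalues -> vibrational frequencies -> quantum-harmonic-oscillator
# entropy, with mode-count bookkeeping.

#' Mode spectrum from a covariance accumulator
#'
#' Diagonalizes the force and torque covariance matrices and converts
#' eigenvalues lambda to frequencies `nu = (1/2pi) sqrt(lambda / kB T)`.
#' At sub-polymer levels (`monomer`, `ua`) the six smallest force
#' eigenvalues are removed: they correspond to rigid translation and
#' rotation of the collection of units, already counted once at the level
#' above. Negative eigenvalues (statistical noise) are clamped to zero and
#' excluded, with a count kept.
#'
#' @param acc An `mcc_covacc` from [accumulate_covariance()].
#' @param temperature Temperature in K (> 0).
#' @return An object of class `mcc_spectrum`: list with `freq_trans`,
#'   `freq_rot` (s^-1, kept modes), `n_kept`, `n_removed`, `n_clamped`,
#'   `level`, `temperature`.
#' @export
spectrum_from_covariance <- function(acc, temperature) {
  if (temperature <= 0) stop("temperature must be positive")
  sub_polymer <- acc$level %in% c("monomer", "ua")
  conv <- function(lambda) {
    # lambda in (kJ/mol/A)^2/amu (forces) or (kJ/mol)^2/(amu A^2) (torques)
    sqrt(lambda * .LAMBDA_SI / (mcc_constants$kB * temperature)) / (2 * pi)
  }
  split_eig <- function(mat, remove6) {
    if (length(mat) == 0 || nrow(mat) == 0)
      return(list(freq = numeric(0), removed = 0L, clamped = 0L))
    lam <- sort(eigen((mat + t(mat)) / 2, symmetric = TRUE,
                      only.values = TRUE)$values, decreasing = TRUE)
    removed <- 0L
    if (remove6) {
      removed <- min(6L, length(lam))
      lam <- lam[seq_len(length(lam) - removed)]
    }
    clamped <- sum(lam <= 0)
    lam <- lam[lam > 0]
    list(freq = conv(lam), removed = removed, clamped = clamped)
  }
  fo <- split_eig(acc$fcov, sub_polymer)
  to <- split_eig(acc$tcov, FALSE)
  structure(list(freq_trans = fo$freq, freq_rot = to$freq,
                 n_kept = length(fo$freq) + length(to$freq),
                 n_removed = fo$removed + to$removed,
                 n_clamped = fo$clamped + to$clamped,
                 level = acc$level, temperature = temperature),
            class = "mcc_spectrum")
}

#' @export
print.mcc_spectrum <- function(x, ...) {
  cat("mcc_spectrum [", x$level, "]: ", length(x$freq_trans), " trans + ",
      length(x$freq_rot), " rot modes kept; ", x$n_removed, " removed, ",
      x$n_clamped, " clamped\n", sep = "")
  invisible(x)
}

#' Quantum-harmonic-oscillator entropy of a mode set
#'
#' Per mode, with `x = h nu / (kB T)`:
#' `S = R * ( x / (exp(x) - 1) - log(1 - exp(-x)) )` in J/K/mol.
#' Zero-frequency modes (removed or clamped) contribute zero by convention,
#' since the expression diverges as `nu -> 0` and such modes are already
#' counted at another level or are pure noise.
#'
#' @param freq Frequencies in s^-1 (numeric vector), or an `mcc_spectrum`.
#' @param temperature Temperature in K.
#' @return For a numeric vector: total entropy in J/K/mol, with attribute
#'   `per_mode`. For an `mcc_spectrum`: list with `S_trans`, `S_rot`,
#'   `S_total` (J/K/mol).
#' @export
qho_entropy <- function(freq, temperature) {
  if (inherits(freq, "mcc_spectrum")) {
    return(list(S_trans = as.numeric(qho_entropy(freq$freq_trans,
                                                 temperature)),
                S_rot = as.numeric(qho_entropy(freq$freq_rot, temperature)),
                S_total = as.numeric(qho_entropy(c(freq$freq_trans,
                                                   freq$freq_rot),
                                                 temperature))))
  }
  if (temperature <= 0) stop("temperature must be positive")
  x <- mcc_constants$h * freq / (mcc_constants$kB * temperature)
  s <- ifelse(x <= 0, 0,
              mcc_constants$R * (x / expm1(x) - log1p(-exp(-x))))
  out <- sum(s)
  attr(out, "per_mode") <- s
  out
}

#' Vibrational entropy of one level in one call
#'
#' Convenience wrapper: accumulate covariances, diagonalize, apply the QHO
#' formula. For `level = "water"` the entropy is per water molecule of the
#' pooled class.
#'
#' @inheritParams accumulate_covariance
#' @return List with `S_trans`, `S_rot`, `S_total` (J/K/mol), `spectrum` and
#'   `accumulator`.
#' @export
vibrational_entropy <- function(frames, hierarchy, level, polymer = NULL,
                                monomer = NULL, waters = NULL,
                                frame_idx = NULL) {
  acc <- accumulate_covariance(frames, hierarchy, level = level,
                               polymer = polymer, monomer = monomer,
                               waters = waters, frame_idx = frame_idx)
  sp <- spectrum_from_covariance(acc, frames$temperature)
  s <- qho_entropy(sp, frames$temperature)
  c(s, list(spectrum = sp, accumulator = acc))
}

#' Export a spectrum as TSV
#'
#' @param spectrum An `mcc_spectrum`.
#' @param path Output path.
#' @param unit Label written into the `unit` column.
#' @return `path`, invisibly.
#' @export
write_spectrum_tsv <- function(spectrum, path, unit = "") {
  freq <- c(spectrum$freq_trans, spectrum$freq_rot)
  kind <- rep(c("trans", "rot"),
              c(length(spectrum$freq_trans), length(spectrum$freq_rot)))
  s <- attr(qho_entropy(freq, spectrum$temperature), "per_mode")
  write_tsv_file(data.frame(level = spectrum$level, unit = unit,
                            mode = seq_along(freq), kind = kind,
                            freq_s1 = freq, S_mode_JKmol = s), path)
}
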