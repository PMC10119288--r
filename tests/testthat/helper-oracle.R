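# Independent brute-force mass oracle built from elemental compositions,
# used to verify all fragment/precursor m/z arithmetic. Kept deliberately
# naive and separate from the package's mass tables.

EL <- c(H = 1.0078250319, C = 12, N = 14.0030740052, O = 15.9949146221,
        S = 31.97207069, P = 30.97376151)

# residue (amino acid minus water) elemental compositions
AA_FORMULA <- list(
  G = c(C = 2, H = 3, N = 1, O = 1), A = c(C = 3, H = 5, N = 1, O = 1),
  S = c(C = 3, H = 5, N = 1, O = 2), P = c(C = 5, H = 7, N = 1, O = 1),
  V = c(C = 5, H = 9, N = 1, O = 1), T = c(C = 4, H = 7, N = 1, O = 2),
  C = c(C = 3, H = 5, N = 1, O = 1, S = 1), L = c(C = 6, H = 11, N = 1, O = 1),
  I = c(C = 6, H = 11, N = 1, O = 1), N = c(C = 4, H = 6, N = 2, O = 2),
  D = c(C = 4, H = 5, N = 1, O = 3), Q = c(C = 5, H = 8, N = 2, O = 2),
  K = c(C = 6, H = 12, N = 2, O = 1), E = c(C = 5, H = 7, N = 1, O = 3),
  M = c(C = 5, H = 9, N = 1, O = 1, S = 1), H = c(C = 6, H = 7, N = 3, O = 1),
  F = c(C = 9, H = 9, N = 1, O = 1), R = c(C = 6, H = 12, N = 4, O = 1),
  Y = c(C = 9, H = 9, N = 1, O = 2), W = c(C = 11, H = 10, N = 2, O = 1))

MOD_FORMULA <- list(
  Phospho = c(H = 1, P = 1, O = 3), Oxidation = c(O = 1),
  Carbamidomethyl = c(C = 2, H = 3, N = 1, O = 1),
  Acetyl = c(C = 2, H = 2, O = 1))

el_mass <- function(counts) sum(EL[names(counts)] * counts)

ORACLE_H2O <- el_mass(c(H = 2, O = 1))
ORACLE_NH3 <- el_mass(c(N = 1, H = 3))
ORACLE_H3PO4 <- el_mass(c(H = 3, P = 1, O = 4))
ORACLE_PROTON <- 1.007276466

oracle_residue_mass <- function(letter) el_mass(AA_FORMULA[[letter]])

oracle_position_masses <- function(p) {
  res <- strsplit(p$sequence, "")[[1]]
  m <- vapply(res, oracle_residue_mass, 0)
  for (i in seq_len(nrow(p$mods))) {
    if (p$mods$pos[i] > 0)
      m[p$mods$pos[i]] <- m[p$mods$pos[i]] + el_mass(MOD_FORMULA[[p$mods$name[i]]])
  }
  m
}

oracle_precursor_mz <- function(p) {
  nterm <- if (any(p$mods$pos == 0)) el_mass(MOD_FORMULA$Acetyl) else 0
  (sum(oracle_position_masses(p)) + nterm + ORACLE_H2O +
     p$charge * ORACLE_PROTON) / p$charge
}

# brute-force fragment m/z; returns NA when the loss class is infeasible
oracle_fragment_mz <- function(p, series, n_h2o, n_nh3, n_p, z, k) {
  m <- oracle_position_masses(p)
  L <- length(m)
  idx <- if (series == "b") seq_len(k) else seq.int(L - k + 1, L)
  nterm <- if (series == "b" && any(p$mods$pos == 0)) el_mass(MOD_FORMULA$Acetyl) else 0
  nph <- sum(p$mods$pos %in% idx & p$mods$name == "Phospho")
  if (nph < n_p) return(NA_real_)
  neutral <- sum(m[idx]) + nterm + (if (series == "y") ORACLE_H2O else 0) -
    n_h2o * ORACLE_H2O - n_nh3 * ORACLE_NH3 - n_p * ORACLE_H3PO4
  if (neutral <= 0) return(NA_real_)
  (neutral + z * ORACLE_PROTON) / z
}

# random peptidoform with optional modifications; relies on the caller
# having seeded the RNG
random_peptidoform <- function(min_len = 5, max_len = 20, max_phospho = 2,
                               with_other_mods = TRUE) {
  repeat {
    len <- sample(min_len:max_len, 1)
    seqc <- paste(sample(names(AA_FORMULA), len, replace = TRUE), collapse = "")
    sty <- which(strsplit(seqc, "")[[1]] %in% c("S", "T", "Y"))
    nph <- sample(0:max_phospho, 1)
    if (length(sty) >= nph) break
  }
  res <- strsplit(seqc, "")[[1]]
  mods <- data.frame(pos = integer(0), name = character(0))
  if (nph > 0)
    mods <- rbind(mods, data.frame(pos = sty[sample.int(length(sty), nph)],
                                   name = "Phospho"))
  if (with_other_mods) {
    mpos <- setdiff(which(res == "M"), mods$pos)
    if (length(mpos) && stats::runif(1) < 0.5)
      mods <- rbind(mods, data.frame(pos = mpos[1], name = "Oxidation"))
    cpos <- setdiff(which(res == "C"), mods$pos)
    if (length(cpos) && stats::runif(1) < 0.5)
      mods <- rbind(mods, data.frame(pos = cpos[1], name = "Carbamidomethyl"))
    if (stats::runif(1) < 0.2)
      mods <- rbind(mods, data.frame(pos = 0, name = "Acetyl"))
  }
  peptidoform(seqc, mods, charge = sample(1:3, 1))
}

# random phosphopeptide guaranteed re-analyzable and decoy-capable
random_phosphopeptide <- function(min_len = 6, max_len = 16, nph = 1) {
  repeat {
    p <- random_peptidoform(min_len, max_len, max_phospho = 0,
                            with_other_mods = FALSE)
    res <- strsplit(p$sequence, "")[[1]]
    sty <- which(res %in% c("S", "T", "Y"))
    if (length(sty) > nph && any(!(res %in% c("S", "T", "Y")))) {
      sites <- sty[sample.int(length(sty), nph)]
      return(peptidoform(p$sequence,
                         data.frame(pos = sites, name = "Phospho"),
                         charge = p$charge))
    }
  }
}
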