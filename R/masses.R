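# Monoisotopic mass constants. Residue masses are amino acid minus water.

.PROTON <- 1.007276466
.H2O    <- 18.0105646863
.NH3    <- 17.0265491015
.H3PO4  <- 97.9768957

.AA_MASS <- c(
  G = 57.02146374, A = 71.03711379, S = 87.03202841, P = 97.05276385,
  V = 99.06841392, T = 101.04767847, C = 103.00918448, L = 113.08406398,
  I = 113.08406398, N = 114.04292744, D = 115.02694302, Q = 128.05857751,
  K = 128.09496302, E = 129.04259309, M = 131.04048461, H = 137.05891186,
  F = 147.06841391, R = 156.10111102, Y = 163.06332853, W = 186.07931295
)

# Supported post-translational modifications and their monoisotopic shifts.
.MOD_DELTA <- c(
  Phospho          = 79.96633089,
  Oxidation        = 15.99491462,
  Carbamidomethyl  = 57.02146374,
  Acetyl           = 42.01056469
)

# Residues each modification may sit on in strict (target) mode; position 0
# denotes the protein N-terminus (Acetyl only).
.MOD_TARGETS <- list(
  Phospho         = c("S", "T", "Y"),
  Oxidation       = "M",
  Carbamidomethyl = "C",
  Acetyl          = character(0)
)

#' Modification mass table
#'
#' Monoisotopic mass shifts of the supported modifications: Phospho (S/T/Y),
#' Oxidation (M), Carbamidomethyl (C) and Acetyl (protein N-terminus).
#'
#' @return Named numeric vector of mass shifts in Da.
#' @export
modification_masses <- function() .MOD_DELTA

#' Residue mass table
#'
#' @return Named numeric vector of monoisotopic residue masses (amino acid
#'   minus water) in Da for the 20 canonical amino acids.
#' @export
residue_masses <- function() .AA_MASS
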