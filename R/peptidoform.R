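#' Construct a peptidoform
#'
#' A peptidoform is a peptide sequence together with positioned modifications
#' and a precursor charge state: the unit of targets, decoys and spectral
#' library entries.
#'
#' Positions are 1-based residue indices; position 0 denotes the protein
#' N-terminus (Acetyl only). At most one modification may occupy a residue
#' position. In strict mode (used for targets) Phospho is restricted to
#' S/T/Y, Oxidation to M and Carbamidomethyl to C; decoy generation relaxes
#' the Phospho restriction so the phosphate can sit on any residue.
#'
#' @param sequence Character scalar of one-letter amino-acid codes.
#' @param mods Data frame with columns `pos` (integer) and `name`
#'   (modification name), or NULL for an unmodified peptide.
#' @param charge Positive integer precursor charge.
#' @param strict Logical; enforce canonical modification target residues.
#' @return An object of class `peptidoform`.
#' @examples
#' peptidoform("STLVLHDLLK", data.frame(pos = 1, name = "Phospho"), charge = 2)
#' @export
peptidoform <- function(sequence, mods = NULL, charge = 2L, strict = TRUE) {
  stopifnot(is.character(sequence), length(sequence) == 1L, nchar(sequence) >= 1L)
  if (nchar(sequence) >= 512L)
    stop("sequence length must be below 512 residues")
  res <- strsplit(sequence, "")[[1]]
  bad <- setdiff(res, names(.AA_MASS))
  if (length(bad))
    stop("unknown residue symbol(s): ", paste(unique(bad), collapse = ", "))
  if (!is.numeric(charge) || length(charge) != 1L || charge < 1)
    stop("charge must be a positive integer")
  if (is.null(mods)) mods <- data.frame(pos = integer(0), name = character(0))
  mods <- data.frame(pos = as.integer(mods$pos), name = as.character(mods$name),
                     stringsAsFactors = FALSE)
  if (nrow(mods)) {
    if (any(is.na(mods$pos)) || any(mods$pos < 0L) || any(mods$pos > length(res)))
      stop("modification position out of range")
    unknown <- setdiff(mods$name, names(.MOD_DELTA))
    if (length(unknown))
      stop("unknown modification(s): ", paste(unique(unknown), collapse = ", "))
    respos <- mods$pos[mods$pos > 0L]
    if (anyDuplicated(respos))
      stop("at most one modification per residue position")
    if (any(mods$name == "Acetyl" & mods$pos != 0L))
      stop("Acetyl is supported on the protein N-terminus (position 0) only")
    if (any(mods$name != "Acetyl" & mods$pos == 0L))
      stop("only Acetyl may occupy the N-terminus position 0")
    if (strict) {
      for (i in which(mods$pos > 0L)) {
        allowed <- .MOD_TARGETS[[mods$name[i]]]
        if (!(res[mods$pos[i]] %in% allowed))
          stop(mods$name[i], " not allowed on residue ", res[mods$pos[i]],
               " at position ", mods$pos[i])
      }
    }
    mods <- mods[order(mods$pos), , drop = FALSE]
    rownames(mods) <- NULL
  }
  structure(list(sequence = sequence, mods = mods, charge = as.integer(charge)),
            class = "peptidoform")
}

#' @export
print.peptidoform <- function(x, ...) {
  cat(format_modified_sequence(x), " (z=", x$charge, ")\n", sep = "")
  invisible(x)
}

#' @export
`==.peptidoform` <- function(e1, e2) {
  identical(format_modified_sequence(e1), format_modified_sequence(e2)) &&
    e1$charge == e2$charge
}

# positions (1-based) carrying a phosphate
phospho_positions <- function(p) p$mods$pos[p$mods$name == "Phospho"]

# number of phosphate groups
phospho_count <- function(p) sum(p$mods$name == "Phospho")

# per-position residue mass including any residue-level modification;
# the N-terminal Acetyl is returned as attribute "nterm"
position_masses <- function(p) {
  m <- unname(.AA_MASS[strsplit(p$sequence, "")[[1]]])
  rmods <- p$mods[p$mods$pos > 0L, , drop = FALSE]
  if (nrow(rmods)) m[rmods$pos] <- m[rmods$pos] + .MOD_DELTA[rmods$name]
  attr(m, "nterm") <- if (any(p$mods$pos == 0L)) .MOD_DELTA[["Acetyl"]] else 0
  m
}

#' Precursor m/z of a peptidoform
#'
#' @param p A `peptidoform`.
#' @param charge Optional charge override; defaults to `p$charge`.
#' @return Monoisotopic precursor m/z in Th:
#'   (sum of residue masses + water + modification shifts + charge protons)
#'   divided by the charge.
#' @examples
#' precursor_mz(peptidoform("AG", charge = 1))  # 147.0764
#' @export
precursor_mz <- function(p, charge = NULL) {
  z <- if (is.null(charge)) p$charge else as.integer(charge)
  stopifnot(z >= 1L)
  m <- position_masses(p)
  (sum(m) + attr(m, "nterm") + .H2O + z * .PROTON) / z
}

# token table for the legacy prefix dialect (longest prefixes first)
.PREFIX_TOKENS <- c(cam = "Carbamidomethyl", ox = "Oxidation", ac = "Acetyl",
                    p = "Phospho")

#' Parse a modified-sequence string
#'
#' Understands the canonical bracket dialect, e.g. `"S[Phospho]TLVLHDLLK"`
#' or `"[Acetyl]-PEPS[Phospho]K"`, and the legacy lowercase-prefix dialect,
#' e.g. `"pSTLVLHDLLK"`, `"oxM"`, `"camC"`.
#'
#' @param text Modified-sequence string.
#' @param charge Precursor charge (default 2).
#' @param strict Enforce canonical modification target residues (disable for
#'   decoy sequences carrying phosphate on non-S/T/Y residues).
#' @return A [peptidoform].
#' @examples
#' parse_modified_sequence("pSTLVLHDLLK", charge = 2)
#' parse_modified_sequence("S[Phospho]AS[Phospho]TK", charge = 2)
#' @export
parse_modified_sequence <- function(text, charge = 2L, strict = TRUE) {
  stopifnot(is.character(text), length(text) == 1L, nzchar(text))
  seq_chars <- character(0)
  pos <- integer(0); name <- character(0)
  s <- text
  if (startsWith(s, "[Acetyl]-")) {
    pos <- c(pos, 0L); name <- c(name, "Acetyl")
    s <- substring(s, nchar("[Acetyl]-") + 1L)
  }
  i <- 1L; n <- nchar(s)
  while (i <= n) {
    ch <- substr(s, i, i)
    if (ch %in% LETTERS) {
      seq_chars <- c(seq_chars, ch)
      i <- i + 1L
      if (i <= n && substr(s, i, i) == "[") {
        close <- regexpr("]", substring(s, i), fixed = TRUE)
        if (close < 0) stop("unterminated modification bracket in: ", text)
        tok <- substr(s, i + 1L, i + close - 2L)
        if (!tok %in% names(.MOD_DELTA))
          stop("unknown modification token: ", tok)
        pos <- c(pos, length(seq_chars)); name <- c(name, tok)
        i <- i + close
      }
    } else {
      hit <- NA_character_
      for (tok in names(.PREFIX_TOKENS)) {
        if (startsWith(substring(s, i), tok)) { hit <- tok; break }
      }
      if (is.na(hit)) stop("unexpected character '", ch, "' in: ", text)
      if (hit == "ac") {
        if (length(seq_chars)) stop("N-terminal acetyl prefix must lead the sequence")
        pos <- c(pos, 0L); name <- c(name, "Acetyl")
        i <- i + 2L
      } else {
        i <- i + nchar(hit)
        if (i > n || !substr(s, i, i) %in% LETTERS)
          stop("modification prefix '", hit, "' not followed by a residue in: ", text)
        seq_chars <- c(seq_chars, substr(s, i, i))
        pos <- c(pos, length(seq_chars)); name <- c(name, .PREFIX_TOKENS[[hit]])
        i <- i + 1L
      }
    }
  }
  peptidoform(paste(seq_chars, collapse = ""),
              data.frame(pos = pos, name = name), charge = charge,
              strict = strict)
}

#' Format a peptidoform as a modified-sequence string
#'
#' Emits the canonical bracket dialect; `parse_modified_sequence()` of the
#' result reproduces the peptidoform.
#'
#' @param p A [peptidoform].
#' @return Character scalar such as `"S[Phospho]TLVLHDLLK"`.
#' @export
format_modified_sequence <- function(p) {
  res <- strsplit(p$sequence, "")[[1]]
  rmods <- p$mods[p$mods$pos > 0L, , drop = FALSE]
  if (nrow(rmods))
    res[rmods$pos] <- paste0(res[rmods$pos], "[", rmods$name, "]")
  out <- paste(res, collapse = "")
  if (any(p$mods$pos == 0L)) out <- paste0("[Acetyl]-", out)
  out
}
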