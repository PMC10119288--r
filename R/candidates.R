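# Candidate database: per spectrum, all positional phosphopeptide isoforms
# of the identified peptide (targets) plus one isobaric decoy per target per
# phosphate, generated by residue exchange (method 1) or phosphate shift
# (method 2).

candidate_site_positions <- function(p) {
  which(strsplit(p$sequence, "")[[1]] %in% c("S", "T", "Y"))
}

#' Enumerate all phosphosite isoforms of a phosphopeptide
#'
#' Generates one peptidoform per size-m subset of the candidate S/T/Y
#' positions, where m is the phosphate count of the input; non-phospho
#' modifications stay in place.
#'
#' @param p A [peptidoform] with at least one phosphate.
#' @return List of [peptidoform]s of length `choose(c, m)` for `c`
#'   candidate sites.
#' @examples
#' length(enumerate_isoforms(parse_modified_sequence("pSTLVLHDLLK")))  # 2
#' @export
enumerate_isoforms <- function(p) {
  m <- phospho_count(p)
  if (m < 1L) stop("peptidoform carries no phosphate")
  sites <- candidate_site_positions(p)
  if (m > length(sites))
    stop("phosphate count exceeds the number of candidate S/T/Y sites")
  other <- p$mods[p$mods$name != "Phospho", , drop = FALSE]
  subsets <- utils::combn(sites, m, simplify = FALSE)
  lapply(subsets, function(ss) {
    mods <- rbind(other, data.frame(pos = ss, name = "Phospho"))
    peptidoform(p$sequence, mods, charge = p$charge)
  })
}

# non-candidate (non-S/T/Y) residue positions
noncandidate_positions <- function(p, exclude_cterm = FALSE) {
  res <- strsplit(p$sequence, "")[[1]]
  pos <- which(!(res %in% c("S", "T", "Y")))
  if (exclude_cterm) pos <- setdiff(pos, nchar(p$sequence))
  pos
}

# swap residues (and their attached mods) at positions i and j
swap_residues <- function(p, i, j) {
  res <- strsplit(p$sequence, "")[[1]]
  tmp <- res[i]; res[i] <- res[j]; res[j] <- tmp
  mods <- p$mods
  at_i <- mods$pos == i
  at_j <- mods$pos == j
  mods$pos[at_i] <- j
  mods$pos[at_j] <- i
  peptidoform(paste(res, collapse = ""), mods, charge = p$charge, strict = FALSE)
}

draw_avoiding <- function(pool, make_decoy, avoid) {
  # redraw up to |pool| times when the decoy collides with an existing
  # candidate, then accept as-is with a warning
  for (attempt in seq_len(max(length(pool), 1L))) {
    j <- if (length(pool) == 1L) pool else sample(pool, 1L)
    d <- make_decoy(j)
    if (!(format_modified_sequence(d) %in% avoid)) return(d)
  }
  warning("decoy collides with an existing candidate; accepted as-is")
  d
}

#' Generate decoys by residue exchange (method 1)
#'
#' For each phosphorylated residue of the target, swaps that residue
#' (phosphate travelling with it, as does any other modification attached
#' to either residue) with a uniformly chosen non-candidate (non-S/T/Y)
#' residue. One decoy per phosphate, so a doubly phosphorylated target
#' yields two decoys. Decoys are isobaric with the target by construction.
#'
#' Uses the current R random number generator state; seed upstream for
#' reproducibility.
#'
#' @param target A [peptidoform] with at least one phosphate.
#' @param avoid Character vector of formatted candidate sequences the decoy
#'   must not duplicate (redrawn, then accepted with a warning).
#' @param exclude_cterm Exclude the C-terminal residue from swapping
#'   (tryptic realism); default FALSE.
#' @return List of decoy [peptidoform]s, one per phosphate.
#' @export
decoy_method1 <- function(target, avoid = character(0), exclude_cterm = FALSE) {
  pool <- noncandidate_positions(target, exclude_cterm)
  if (!length(pool))
    stop("decoy generation failed: no non-candidate residue in sequence")
  lapply(phospho_positions(target), function(i) {
    draw_avoiding(pool, function(j) swap_residues(target, i, j), avoid)
  })
}

#' Generate decoys by phosphate shift (method 2)
#'
#' For each phosphate of the target, moves the phosphate to a uniformly
#' chosen non-candidate (non-S/T/Y) position, leaving the sequence
#' unchanged; the decoy carries a phosphate on a non-canonical residue.
#' Positions already occupied by another modification are not used.
#'
#' @inheritParams decoy_method1
#' @return List of decoy [peptidoform]s, one per phosphate.
#' @export
decoy_method2 <- function(target, avoid = character(0), exclude_cterm = FALSE) {
  pool <- noncandidate_positions(target, exclude_cterm)
  pool <- setdiff(pool, target$mods$pos)
  if (!length(pool))
    stop("decoy generation failed: no unmodified non-candidate residue in sequence")
  lapply(phospho_positions(target), function(i) {
    make <- function(j) {
      mods <- target$mods
      mods$pos[mods$pos == i & mods$name == "Phospho"] <- j
      peptidoform(target$sequence, mods, charge = target$charge, strict = FALSE)
    }
    draw_avoiding(pool, make, avoid)
  })
}

#' Read a database-search identification table
#'
#' Tab-separated table with one row per identified phosphopeptide spectrum.
#' Required content: spectrum id, modified sequence, precursor charge and
#' localization probability; common export headers from other tools are
#' mapped automatically, or supply `col_map`.
#'
#' @param path Path to a TSV file (lines starting with `#` are skipped).
#' @param col_map Optional named character vector mapping the canonical
#'   names `spectrum_id`, `modified_sequence`, `charge`,
#'   `localization_probability` to the file's headers.
#' @return Data frame with canonical column names.
#' @export
read_search_results <- function(path, col_map = NULL) {
  df <- utils::read.delim(path, comment.char = "#", stringsAsFactors = FALSE,
                          check.names = FALSE)
  aliases <- list(
    spectrum_id = c("spectrum_id", "Spectrum", "Title", "Raw file.Scan"),
    modified_sequence = c("modified_sequence", "Modified sequence",
                          "ModifiedPeptide", "EG.ModifiedSequence"),
    charge = c("charge", "Charge", "FG.Charge"),
    localization_probability = c("localization_probability",
                                 "Localization prob", "PTMLocalizationProbability",
                                 "EG.PTMLocalizationProbabilities"))
  for (canon in names(aliases)) {
    have <- if (!is.null(col_map) && canon %in% names(col_map)) col_map[[canon]]
            else intersect(aliases[[canon]], names(df))[1]
    if (is.na(have) || is.null(have) || !(have %in% names(df))) {
      if (canon == "localization_probability") { df[[canon]] <- NA_real_; next }
      stop("search-result table lacks a '", canon, "' column")
    }
    names(df)[names(df) == have] <- canon
  }
  df
}

#' Build the per-spectrum candidate database
#'
#' For every identification: parse the reported peptidoform, enumerate all
#' phosphosite isoforms (targets), and generate one decoy per target per
#' phosphate by the chosen method. Spectra whose peptide offers no
#' alternative site (candidate S/T/Y count equal to the phosphate count)
#' are not re-analyzable and are kept in a pass-through list. Rows with
#' more phosphates than `max_phospho` are dropped with a message.
#'
#' @param identifications Data frame as from [read_search_results()].
#' @param method Decoy generation method, 1 (residue exchange) or 2
#'   (phosphate shift).
#' @param seed Optional integer seed for the decoy draws.
#' @param max_phospho Maximum supported phosphate count (default 2).
#' @param exclude_cterm Passed to the decoy generators.
#' @return Object of class `candidate_db`: list with `sets` (per-spectrum
#'   candidate sets), `passthrough` (non-reanalyzable rows), `n_target`,
#'   `n_decoy`, `n_dropped`, `method`, `seed`.
#' @export
build_candidate_database <- function(identifications, method = 1L, seed = NULL,
                                     max_phospho = 2L, exclude_cterm = FALSE) {
  stopifnot(method %in% c(1L, 2L))
  if (!is.null(seed)) set.seed(seed)
  gen <- if (method == 1L) decoy_method1 else decoy_method2
  sets <- list(); passthrough <- list(); bad <- integer(0)
  n_dropped <- 0L
  for (r in seq_len(nrow(identifications))) {
    row <- identifications[r, ]
    p <- tryCatch(parse_modified_sequence(row$modified_sequence,
                                          charge = row$charge),
                  error = function(e) NULL)
    if (is.null(p) || phospho_count(p) < 1L) { bad <- c(bad, r); next }
    if (phospho_count(p) > max_phospho) { n_dropped <- n_dropped + 1L; next }
    nsites <- length(candidate_site_positions(p))
    if (nsites <= phospho_count(p)) {
      passthrough[[length(passthrough) + 1L]] <-
        list(spectrum_id = row$spectrum_id, peptidoform = p)
      next
    }
    targets <- enumerate_isoforms(p)
    avoid <- vapply(targets, format_modified_sequence, "")
    decoys <- list(); parent <- integer(0)
    for (ti in seq_along(targets)) {
      ds <- gen(targets[[ti]], avoid = avoid, exclude_cterm = exclude_cterm)
      avoid <- c(avoid, vapply(ds, format_modified_sequence, ""))
      decoys <- c(decoys, ds)
      parent <- c(parent, rep(ti, length(ds)))
    }
    sets[[length(sets) + 1L]] <- structure(
      list(spectrum_id = row$spectrum_id, engine_peptidoform = p,
           targets = targets, decoys = decoys, decoy_parent = parent,
           reanalyzable = TRUE), class = "candidate_set")
  }
  if (length(bad))
    warning("skipped ", length(bad), " malformed/non-phospho row(s): ",
            paste(utils::head(bad, 10), collapse = ", "))
  if (n_dropped)
    message("dropped ", n_dropped, " row(s) with more than ", max_phospho,
            " phosphates")
  n_target <- sum(vapply(sets, function(s) length(s$targets), 0L))
  n_decoy <- sum(vapply(sets, function(s) length(s$decoys), 0L))
  if (length(sets) == 0L && length(passthrough) == 0L)
    stop("empty candidate database: no usable identifications")
  structure(list(sets = sets, passthrough = passthrough,
                 n_target = n_target, n_decoy = n_decoy,
                 n_dropped = n_dropped, method = method, seed = seed),
            class = "candidate_db")
}

#' @export
print.candidate_db <- function(x, ...) {
  cat("Candidate database (decoy method ", x$method, "): ",
      length(x$sets), " re-analyzable spectra, ",
      x$n_target, " targets, ", x$n_decoy, " decoys, ",
      length(x$passthrough), " pass-through\n", sep = "")
  invisible(x)
}
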