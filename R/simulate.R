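# Ground-truthed synthetic phosphoproteome generator: tryptic-like
# phosphopeptides, noisy MS/MS spectra derived from a deterministic
# predictor, and an imperfect search-engine identification table, all
# cross-keyed by spectrum id. Stands in for instrument data so the whole
# pipeline is testable end to end.

#' Simulation configuration
#'
#' Defaults emulate a good-quality orbitrap DDA phosphoproteome run: mostly
#' mono-phosphorylated tryptic peptides, substantial peak dropout and
#' intensity scatter, m/z jitter well inside the 25 ppm matching tolerance,
#' a few contaminant peaks, and a search engine that mislocalizes 10% of
#' sites.
#'
#' @param n_peptides Number of peptides (one spectrum each).
#' @param length_range Min/max peptide length.
#' @param phospho_probs Named probabilities of phosphate counts
#'   (default mono 0.9, di 0.1).
#' @param sty_density Expected fraction of S/T/Y among internal residues.
#' @param charge_probs Named probabilities of precursor charges.
#' @param dropout Per-peak dropout probability.
#' @param intensity_sigma Log-normal multiplicative intensity noise sigma.
#' @param mz_jitter_ppm Gaussian m/z jitter sigma in ppm (keep below a
#'   third of the matching tolerance so true peaks usually match).
#' @param n_contaminants Contaminant peaks per spectrum.
#' @param contaminant_scale Contaminant intensity ceiling relative to the
#'   base peak.
#' @param mislocalization Fraction of spectra whose engine-reported site
#'   assignment is wrong.
#' @param seed Integer RNG seed.
#' @return List of class `sim_config`.
#' @export
sim_config <- function(n_peptides = 100L, length_range = c(8L, 16L),
                       phospho_probs = c("1" = 0.9, "2" = 0.1),
                       sty_density = 0.25,
                       charge_probs = c("2" = 0.7, "3" = 0.3),
                       dropout = 0.3, intensity_sigma = 0.5,
                       mz_jitter_ppm = 5, n_contaminants = 12L,
                       contaminant_scale = 0.2, mislocalization = 0.1,
                       seed = 1L) {
  stopifnot(dropout >= 0, dropout <= 1, mislocalization >= 0,
            mislocalization <= 1, sty_density > 0, sty_density < 1,
            abs(sum(phospho_probs) - 1) < 1e-8)
  if (mz_jitter_ppm >= 25 / 3)
    warning("m/z jitter of ", mz_jitter_ppm,
            " ppm approaches the 25 ppm matching tolerance; true peaks may miss")
  structure(list(n_peptides = as.integer(n_peptides),
                 length_range = as.integer(length_range),
                 phospho_probs = phospho_probs, sty_density = sty_density,
                 charge_probs = charge_probs, dropout = dropout,
                 intensity_sigma = intensity_sigma,
                 mz_jitter_ppm = mz_jitter_ppm,
                 n_contaminants = as.integer(n_contaminants),
                 contaminant_scale = contaminant_scale,
                 mislocalization = mislocalization, seed = as.integer(seed)),
            class = "sim_config")
}

# residue alphabet for internal positions: no K/R (tryptic-like), S/T/Y at
# the configured density
.internal_residue_weights <- function(sty_density) {
  others <- setdiff(names(.AA_MASS), c("K", "R", "S", "T", "Y"))
  w <- c(stats::setNames(rep((1 - sty_density) / length(others), length(others)),
                         others),
         S = sty_density * 0.4, T = sty_density * 0.4, Y = sty_density * 0.2)
  w
}

#' Simulate ground-truthed phosphopeptides
#'
#' Tryptic-like sequences (C-terminal K/R, no internal K/R) with known
#' phosphosites drawn uniformly among the candidate S/T/Y positions. Every
#' peptide carries more candidate sites than phosphates, so its spectrum is
#' re-analyzable.
#'
#' @param config A [sim_config()]. Uses the current RNG state; seed
#'   upstream (as [simulate_dataset()] does).
#' @return List of [peptidoform]s; ground-truth sites are the phosphates
#'   they carry.
#' @export
simulate_peptides <- function(config) {
  w <- .internal_residue_weights(config$sty_density)
  out <- vector("list", config$n_peptides)
  for (i in seq_len(config$n_peptides)) {
    nph <- as.integer(sample(names(config$phospho_probs), 1L,
                             prob = config$phospho_probs))
    repeat {
      len <- sample(config$length_range[1]:config$length_range[2], 1L)
      body <- sample(names(w), len - 1L, replace = TRUE, prob = w)
      seqc <- paste(c(body, sample(c("K", "R"), 1L)), collapse = "")
      cand <- which(strsplit(seqc, "")[[1]] %in% c("S", "T", "Y"))
      if (length(cand) > nph) break   # re-analyzable by construction
    }
    sites <- sort(sample(cand, nph))
    z <- as.integer(sample(names(config$charge_probs), 1L,
                           prob = config$charge_probs))
    out[[i]] <- peptidoform(seqc, data.frame(pos = sites, name = "Phospho"),
                            charge = z)
  }
  out
}

#' Simulate a noisy MS/MS spectrum of a phosphopeptide
#'
#' Starts from the predictor's spectrum of the true isoform, drops each
#' peak independently, applies log-normal intensity noise and Gaussian ppm
#' m/z jitter, and adds uniform contaminant peaks.
#'
#' @param p The true [peptidoform].
#' @param predictor A deterministic spectrum predictor.
#' @param config A [sim_config()] (noise fields used).
#' @param spectrum_id Identifier for the spectrum.
#' @return An [ms_spectrum] (possibly empty when dropout is 1).
#' @export
simulate_spectrum <- function(p, predictor, config, spectrum_id = "sim") {
  pred <- predict_spectrum(predictor, p)
  pred <- pred[pred$intensity > 0, , drop = FALSE]
  keep <- stats::runif(nrow(pred)) >= config$dropout
  mz <- pred$mz[keep]
  it <- pred$intensity[keep] *
    stats::rlnorm(sum(keep), 0, config$intensity_sigma)
  mz <- mz * (1 + stats::rnorm(length(mz), 0, config$mz_jitter_ppm * 1e-6))
  if (config$n_contaminants > 0) {
    top <- if (length(it)) max(it) else 1
    cm <- stats::runif(config$n_contaminants, 100,
                       max(1000, precursor_mz(p) * p$charge))
    ci <- stats::runif(config$n_contaminants, 0,
                       config$contaminant_scale * top)
    mz <- c(mz, cm); it <- c(it, ci)
  }
  ms_spectrum(spectrum_id, mz, it, precursor_mz = precursor_mz(p),
              precursor_charge = p$charge,
              rt = stats::runif(1, 0, 7200))
}

#' Simulate a complete ground-truthed dataset
#'
#' Generates peptides, their noisy spectra, an imperfect search-engine
#' identification table (a configurable fraction of spectra reported with
#' a wrong site), and the ground truth, all keyed by spectrum id and fully
#' reproducible from the seed. Optionally writes `spectra.mgf`, `ids.tsv`
#' and `truth.tsv` (the seed recorded in a header comment).
#'
#' @param config A [sim_config()].
#' @param predictor Spectrum predictor (default [baseline_predictor()]).
#' @param dir Optional output directory (created if needed).
#' @return Invisible list: `spectra`, `ids` (search-result table),
#'   `truth`, `peptides`.
#' @export
simulate_dataset <- function(config, predictor = baseline_predictor(),
                             dir = NULL) {
  set.seed(config$seed)
  peptides <- simulate_peptides(config)
  n <- length(peptides)
  ids <- paste0("sim_", sprintf("%05d", seq_len(n)))
  spectra <- vector("list", n)
  reported <- true_seq <- character(n)
  misloc <- stats::runif(n) < config$mislocalization
  for (i in seq_len(n)) {
    p <- peptides[[i]]
    spectra[[i]] <- simulate_spectrum(p, predictor, config, spectrum_id = ids[i])
    true_seq[i] <- format_modified_sequence(p)
    rep_p <- p
    if (misloc[i]) {
      iso <- enumerate_isoforms(p)
      wrong <- Filter(function(q) !(q == p), iso)
      if (length(wrong)) rep_p <- wrong[[sample.int(length(wrong), 1L)]]
    }
    reported[i] <- format_modified_sequence(rep_p)
  }
  loc_prob <- round(ifelse(misloc, stats::runif(n, 0.3, 0.8),
                           stats::runif(n, 0.6, 1.0)), 3)
  ids_df <- data.frame(spectrum_id = ids,
                       sequence = vapply(peptides, `[[`, "", "sequence"),
                       modified_sequence = reported,
                       charge = vapply(peptides, `[[`, 0L, "charge"),
                       localization_probability = loc_prob,
                       stringsAsFactors = FALSE)
  truth_df <- data.frame(spectrum_id = ids, modified_sequence = true_seq,
                         stringsAsFactors = FALSE)
  if (!is.null(dir)) {
    dir.create(dir, showWarnings = FALSE, recursive = TRUE)
    write_mgf(spectra, file.path(dir, "spectra.mgf"))
    hdr <- paste0("# seed: ", config$seed)
    for (nm in c("ids", "truth")) {
      path <- file.path(dir, paste0(nm, ".tsv"))
      writeLines(hdr, path)
      suppressWarnings(utils::write.table(
        if (nm == "ids") ids_df else truth_df, path, sep = "\t",
        quote = FALSE, row.names = FALSE, append = TRUE))
    }
  }
  invisible(list(spectra = spectra, ids = ids_df, truth = truth_df,
                 peptides = peptides))
}
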