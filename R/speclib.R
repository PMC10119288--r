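# DIA spectral-library construction in three modes:
#   predicted    - every entry carries predictor intensities
#   hybrid       - predictor intensities only where the re-localized site
#                  assignment differs from the search engine's, experimental
#                  intensities (annotated on the 36-type grid) elsewhere
#   relocalized  - experimental intensities throughout, re-localized
#                  peptidoform identifications
# Retention times always come from the experiment.

#' Build a DIA spectral library from FLR-accepted identifications
#'
#' @param accepted Data frame of accepted target PSMs (e.g.
#'   `threshold_at_flr(...)$accepted`); decoy hits are dropped.
#' @param spectra List of [ms_spectrum] indexed by spectrum id.
#' @param predictor Spectrum predictor used for predicted intensities.
#' @param mode One of `"predicted"`, `"hybrid"`, `"relocalized"`.
#' @param engine Optional search-result data frame giving the engine's
#'   original `modified_sequence` per `spectrum_id`; required for
#'   `"hybrid"`.
#' @param params [matching_params()] used to annotate experimental
#'   intensities on the fragment grid.
#' @param min_fragments Entries with fewer nonzero fragments are dropped
#'   (default 4).
#' @return Data frame, one fragment per row: `modified_sequence`,
#'   `precursor_charge`, `precursor_mz`, `fragment_type`,
#'   `fragment_series`, `fragment_loss`, `fragment_index`,
#'   `fragment_charge`, `fragment_mz`, `relative_intensity`,
#'   `retention_time`, `provenance`.
#' @export
build_library <- function(accepted, spectra, predictor = baseline_predictor(),
                          mode = c("predicted", "hybrid", "relocalized"),
                          engine = NULL, params = matching_params(),
                          min_fragments = 4L) {
  mode <- match.arg(mode)
  if (mode == "hybrid" && is.null(engine))
    stop("hybrid mode needs the engine's original identifications")
  accepted <- accepted[!accepted$is_decoy, , drop = FALSE]
  by_id <- stats::setNames(spectra, vapply(spectra, `[[`, "", "spectrum_id"))
  # duplicate peptidoform+charge: keep the highest-cosine PSM
  accepted <- accepted[order(-accepted$cosine), , drop = FALSE]
  out <- list(); n_missing <- 0L; n_thin <- 0L
  seen <- character(0)
  for (r in seq_len(nrow(accepted))) {
    row <- accepted[r, ]
    s <- by_id[[row$spectrum_id]]
    if (is.null(s)) { n_missing <- n_missing + 1L; next }
    p <- parse_modified_sequence(row$peptidoform,
                                 charge = if (!is.na(s$precursor_charge))
                                   s$precursor_charge else 2L,
                                 strict = FALSE)
    key <- paste(row$peptidoform, p$charge, sep = "/")
    if (key %in% seen) next
    seen <- c(seen, key)
    grid <- theoretical_spectrum(p)
    use_predicted <- switch(mode,
      predicted = TRUE,
      relocalized = FALSE,
      hybrid = {
        eng <- engine$modified_sequence[match(row$spectrum_id, engine$spectrum_id)]
        eng_fmt <- tryCatch(
          format_modified_sequence(parse_modified_sequence(eng, charge = p$charge)),
          error = function(e) NA_character_)
        !identical(eng_fmt, row$peptidoform)
      })
    if (use_predicted) {
      pred <- predict_spectrum(predictor, p, grid = grid)
      intensity <- pred$intensity
      provenance <- "predicted"
    } else {
      intensity <- match_peaks(grid$mz, s, params)
      if (max(intensity) > 0) intensity <- intensity / max(intensity)
      provenance <- "experimental"
    }
    keep <- intensity > 0
    if (sum(keep) < min_fragments) { n_thin <- n_thin + 1L; next }
    out[[length(out) + 1L]] <- data.frame(
      modified_sequence = row$peptidoform, precursor_charge = p$charge,
      precursor_mz = precursor_mz(p),
      fragment_type = grid$label[keep], fragment_series = grid$series[keep],
      fragment_loss = grid$loss[keep], fragment_index = grid$cleavage[keep],
      fragment_charge = grid$frag_charge[keep], fragment_mz = grid$mz[keep],
      relative_intensity = intensity[keep],
      retention_time = s$rt, provenance = provenance,
      stringsAsFactors = FALSE)
  }
  if (n_missing) warning(n_missing, " PSM(s) dropped: spectrum missing")
  if (n_thin) message(n_thin, " entr(ies) dropped below ", min_fragments,
                      " fragments")
  if (!length(out)) stop("library is empty")
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Write a spectral library to a flat TSV
#'
#' One fragment per row, vendor-neutral Spectronaut-style dialect.
#'
#' @param library Data frame from [build_library()].
#' @param path Output path.
#' @export
write_speclib <- function(library, path) {
  utils::write.table(library, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Read a spectral library TSV
#'
#' @param path Path written by [write_speclib()] or an external table with
#'   the same columns (`fragment_type` + `fragment_index` keyed).
#' @return Data frame suitable for [library_predictor()].
#' @export
read_speclib <- function(path) {
  utils::read.delim(path, stringsAsFactors = FALSE)
}
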