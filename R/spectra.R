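#' Construct an experimental MS/MS spectrum
#'
#' A centroided peak list with precursor information. Peaks are stored
#' sorted by ascending m/z.
#'
#' @param spectrum_id Character identifier (MGF TITLE).
#' @param mz Numeric vector of peak m/z values in Th.
#' @param intensity Numeric vector of non-negative intensities.
#' @param precursor_mz Precursor m/z in Th.
#' @param precursor_charge Integer precursor charge, or NA when unknown.
#' @param rt Optional retention time (seconds), NA when absent.
#' @return An object of class `ms_spectrum`.
#' @export
ms_spectrum <- function(spectrum_id, mz, intensity, precursor_mz = NA_real_,
                        precursor_charge = NA_integer_, rt = NA_real_) {
  stopifnot(length(mz) == length(intensity))
  if (any(intensity < 0)) stop("intensities must be non-negative")
  o <- order(mz)
  structure(list(spectrum_id = as.character(spectrum_id),
                 precursor_mz = as.numeric(precursor_mz),
                 precursor_charge = as.integer(precursor_charge),
                 rt = as.numeric(rt),
                 mz = as.numeric(mz[o]), intensity = as.numeric(intensity[o])),
            class = "ms_spectrum")
}

#' @export
print.ms_spectrum <- function(x, ...) {
  cat("MS/MS spectrum '", x$spectrum_id, "': ", length(x$mz), " peaks",
      if (!is.na(x$precursor_mz))
        sprintf(", precursor %.4f Th (z=%s)", x$precursor_mz,
                ifelse(is.na(x$precursor_charge), "?", x$precursor_charge)),
      "\n", sep = "")
  invisible(x)
}

#' Read spectra from a Mascot generic format (MGF) file
#'
#' Parses BEGIN IONS/END IONS blocks with TITLE, PEPMASS, CHARGE and
#' optional RTINSECONDS headers. Blocks missing CHARGE are kept with the
#' charge recorded as NA; malformed or empty blocks are skipped with a
#' warning.
#'
#' @param path Path to an MGF file.
#' @return List of [ms_spectrum] objects.
#' @export
read_mgf <- function(path) {
  lines <- readLines(path)
  starts <- which(lines == "BEGIN IONS")
  ends <- which(lines == "END IONS")
  if (length(starts) == 0L || length(starts) != length(ends))
    stop("no complete MGF blocks found in ", path)
  spectra <- vector("list", length(starts))
  kept <- 0L
  for (b in seq_along(starts)) {
    block <- lines[(starts[b] + 1L):(ends[b] - 1L)]
    title <- sub("^TITLE=", "", grep("^TITLE=", block, value = TRUE)[1])
    pep <- grep("^PEPMASS=", block, value = TRUE)
    chg <- grep("^CHARGE=", block, value = TRUE)
    rt <- grep("^RTINSECONDS=", block, value = TRUE)
    peak_lines <- block[grepl("^[0-9]", block)]
    if (is.na(title) || length(peak_lines) == 0L) {
      warning("skipping malformed MGF block ", b, " in ", path)
      next
    }
    pm <- if (length(pep)) as.numeric(strsplit(sub("^PEPMASS=", "", pep[1]),
                                               "[ \t]")[[1]][1]) else NA_real_
    z <- if (length(chg)) {
      zs <- sub("^CHARGE=", "", chg[1])
      as.integer(sub("\\+$", "", zs)) * if (grepl("-$", zs)) -1L else 1L
    } else NA_integer_
    rtv <- if (length(rt)) as.numeric(sub("^RTINSECONDS=", "", rt[1])) else NA_real_
    fields <- strsplit(peak_lines, "[ \t]+")
    mz <- vapply(fields, function(f) as.numeric(f[1]), 0)
    it <- vapply(fields, function(f) as.numeric(f[2]), 0)
    if (anyNA(mz) || anyNA(it)) {
      warning("skipping MGF block ", b, " with unparseable peaks in ", path)
      next
    }
    kept <- kept + 1L
    spectra[[kept]] <- ms_spectrum(title, mz, it, precursor_mz = pm,
                                   precursor_charge = z, rt = rtv)
  }
  if (kept == 0L) stop("no readable spectra in ", path)
  spectra[seq_len(kept)]
}

#' Write spectra to a Mascot generic format (MGF) file
#'
#' @param spectra List of [ms_spectrum] objects.
#' @param path Output path.
#' @param digits_mz Decimal places printed for m/z (default 4).
#' @param digits_intensity Decimal places printed for intensity (default 1).
#' @export
write_mgf <- function(spectra, path, digits_mz = 4L, digits_intensity = 1L) {
  if (inherits(spectra, "ms_spectrum")) spectra <- list(spectra)
  con <- file(path, "w")
  on.exit(close(con))
  for (s in spectra) {
    writeLines("BEGIN IONS", con)
    writeLines(paste0("TITLE=", s$spectrum_id), con)
    if (!is.na(s$precursor_mz))
      writeLines(sprintf("PEPMASS=%.*f", digits_mz, s$precursor_mz), con)
    if (!is.na(s$precursor_charge))
      writeLines(sprintf("CHARGE=%d+", s$precursor_charge), con)
    if (!is.na(s$rt)) writeLines(sprintf("RTINSECONDS=%.3f", s$rt), con)
    if (length(s$mz))
      writeLines(sprintf("%.*f %.*f", digits_mz, s$mz,
                         digits_intensity, s$intensity), con)
    writeLines(c("END IONS", ""), con)
  }
  invisible(path)
}

#' Matching parameters for spectral comparison
#'
#' @param tolerance_ppm Peak-matching tolerance in parts per million
#'   (default 25).
#' @param missing_value Intensity assigned to theoretical ions with no
#'   experimental peak within tolerance (default 0).
#' @param transform Intensity transform applied before similarity scoring:
#'   `"raw"` (max-normalized, the default) or `"normalized_log"`
#'   (max-normalized then log2(x + 1)).
#' @return List of class `matching_params`.
#' @export
matching_params <- function(tolerance_ppm = 25, missing_value = 0,
                            transform = c("raw", "normalized_log")) {
  stopifnot(tolerance_ppm > 0)
  structure(list(tolerance_ppm = tolerance_ppm, missing_value = missing_value,
                 transform = match.arg(transform)), class = "matching_params")
}

#' Normalize fragment intensities
#'
#' Scales intensities to the 0-1 range by the maximum, then applies
#' log2(x + 1), mapping back into the 0-1 range. The transform is monotone,
#' so peak ranks are preserved.
#'
#' @param v Non-negative numeric vector with at least one positive value.
#' @return Numeric vector in the 0-1 range.
#' @export
normalize_intensities <- function(v) {
  if (!length(v) || max(v) <= 0) stop("cannot normalize an all-zero intensity vector")
  log2(v / max(v) + 1)
}

#' Align experimental peak intensities to a theoretical fragment grid
#'
#' For each theoretical m/z, finds the closest experimental peak within the
#' ppm tolerance and returns its intensity; theoretical ions with no peak in
#' tolerance receive `missing_value`. An experimental peak may serve several
#' theoretical ions; ties are broken by smallest ppm error.
#'
#' @param theoretical Numeric vector of theoretical fragment m/z, or a data
#'   frame with an `mz` column as returned by [theoretical_spectrum()].
#' @param spectrum An [ms_spectrum].
#' @param params A [matching_params] object.
#' @return Numeric vector of matched experimental intensities, parallel to
#'   `theoretical`.
#' @export
match_peaks <- function(theoretical, spectrum, params = matching_params()) {
  tmz <- if (is.data.frame(theoretical)) theoretical$mz else as.numeric(theoretical)
  n <- length(tmz)
  out <- rep(params$missing_value, n)
  emz <- spectrum$mz
  if (!length(emz) || !n) return(out)
  idx <- findInterval(tmz, emz)
  lo <- pmax(idx, 1L)
  hi <- pmin(idx + 1L, length(emz))
  err_lo <- abs(emz[lo] - tmz) / tmz * 1e6
  err_hi <- abs(emz[hi] - tmz) / tmz * 1e6
  use_hi <- err_hi < err_lo
  best <- ifelse(use_hi, hi, lo)
  err <- pmin(err_lo, err_hi)
  ok <- err <= params$tolerance_ppm
  out[ok] <- spectrum$intensity[best[ok]]
  out
}

#' Cosine similarity between two aligned intensity vectors
#'
#' @param a,b Numeric vectors on the same fragment grid.
#' @return dot(a, b) / (||a|| ||b||), in the 0-1 range for non-negative
#'   vectors; 0 (with a message) when either vector is all zero.
#' @export
cosine_similarity <- function(a, b) {
  if (length(a) != length(b)) stop("intensity vectors differ in length")
  na <- sqrt(sum(a^2)); nb <- sqrt(sum(b^2))
  if (na == 0 || nb == 0) {
    message("all-zero intensity vector; cosine similarity set to 0")
    return(0)
  }
  sum(a * b) / (na * nb)
}

#' Pearson correlation between two aligned intensity vectors
#'
#' @param a,b Numeric vectors of equal length >= 2, neither constant.
#' @return Product-moment correlation coefficient in [-1, 1].
#' @export
pearson_correlation <- function(a, b) {
  if (length(a) != length(b)) stop("intensity vectors differ in length")
  if (length(a) < 2L) stop("need at least two values")
  if (stats::sd(a) == 0 || stats::sd(b) == 0)
    stop("correlation undefined for a constant intensity vector")
  stats::cor(a, b)
}
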