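# Spectrum predictors. Any object for which a predict_spectrum() method
# exists and that returns non-negative intensities on the 36-type fragment
# grid (zero for infeasible ions) can drive the FLR machinery.

#' Predict fragment intensities for a peptidoform
#'
#' Generic predictor contract: given a peptidoform, return its feasible
#' theoretical fragment grid with a predicted relative intensity per ion.
#'
#' @param predictor A predictor object ([baseline_predictor] or
#'   [library_predictor]).
#' @param p A [peptidoform].
#' @param grid Optional precomputed [theoretical_spectrum()] of `p`, to
#'   avoid recomputation in scoring loops.
#' @return Data frame: the theoretical grid plus an `intensity` column in
#'   the 0-1 range, or NULL when a library predictor has no entry for `p`.
#' @export
predict_spectrum <- function(predictor, p, grid = NULL) {
  UseMethod("predict_spectrum")
}

#' Deterministic rule-based spectrum predictor
#'
#' A fully deterministic surrogate for a learned fragment-intensity model.
#' Backbone b/y intensities follow a unimodal profile over the cleavage
#' index peaking at mid-sequence; each neutral-loss peak is a fixed fraction
#' of its parent ion; doubly charged fragments are a fixed fraction of the
#' singly charged ones; the spectrum is renormalized to a maximum of 1.
#'
#' The phosphoric-acid loss fraction depends on which residue carries the
#' phosphate: phospho-S/T lose H3PO4 readily, phospho-Y weakly. Phosphate
#' on a non-canonical residue (decoy peptidoforms) is treated like S/T, so
#' targets and decoys are handled symmetrically. For double losses the
#' per-site fractions multiply.
#'
#' @param b_weight,y_weight Relative scale of the b and y series.
#' @param width_frac Width of the unimodal cleavage profile as a fraction
#'   of peptide length.
#' @param h2o_factor,nh3_factor Intensity fraction of -H2O and -NH3 peaks
#'   relative to the parent ion.
#' @param p_factor_st,p_factor_y H3PO4-loss fraction for phosphate on
#'   S/T (or non-canonical residues) and on Y, respectively.
#' @param charge2_factor Intensity of 2+ fragments relative to 1+.
#' @return Predictor object of class `baseline_predictor`.
#' @export
baseline_predictor <- function(b_weight = 0.7, y_weight = 1.0,
                               width_frac = 0.35,
                               h2o_factor = 0.2, nh3_factor = 0.2,
                               p_factor_st = 0.5, p_factor_y = 0.1,
                               charge2_factor = 0.3) {
  structure(list(b_weight = b_weight, y_weight = y_weight,
                 width_frac = width_frac, h2o_factor = h2o_factor,
                 nh3_factor = nh3_factor, p_factor_st = p_factor_st,
                 p_factor_y = p_factor_y, charge2_factor = charge2_factor,
                 name = "baseline", deterministic = TRUE),
            class = "baseline_predictor")
}

# intensity vector for a .theo_core() grid (feasible ions, aligned order)
.baseline_intensity <- function(cfg, p, core) {
  L <- core$length
  base_profile <- exp(-0.5 * ((seq_len(L - 1L) - L / 2) / (cfg$width_frac * L))^2)
  # per-position H3PO4-loss propensity of a phosphate at that position
  prop <- numeric(L)
  php <- phospho_positions(p)
  if (length(php)) {
    res <- strsplit(p$sequence, "")[[1]][php]
    prop[php] <- ifelse(res == "Y", cfg$p_factor_y, cfg$p_factor_st)
  }
  # running largest and product-of-two-largest propensities over the b
  # prefix / y suffix at each cleavage
  top2 <- function(v) {
    one <- two <- numeric(length(v)); t1 <- t2 <- 0
    for (i in seq_along(v)) {
      x <- v[i]
      if (x >= t1) { t2 <- t1; t1 <- x } else if (x > t2) t2 <- x
      one[i] <- t1; two[i] <- t1 * t2
    }
    list(one = one, two = two)
  }
  bf <- top2(prop[seq_len(L - 1L)])
  yf <- top2(rev(prop)[seq_len(L - 1L)])
  ft <- .fragment_types_table()
  np <- ft$n_phospho_loss[core$ti]
  kk <- core$cleavage
  sb <- core$series_b
  pfac <- rep(1, length(kk))
  i1 <- np == 1L; i2 <- np == 2L
  pfac[i1] <- ifelse(sb[i1], bf$one[kk[i1]], yf$one[kk[i1]])
  pfac[i2] <- ifelse(sb[i2], bf$two[kk[i2]], yf$two[kk[i2]])
  series_w <- rep(cfg$y_weight, length(kk)); series_w[sb] <- cfg$b_weight
  z2 <- ft$frag_charge[core$ti] == 2L
  chg <- rep(1, length(kk)); chg[z2] <- cfg$charge2_factor
  intensity <- series_w * base_profile[kk] *
    cfg$h2o_factor^ft$n_h2o[core$ti] * cfg$nh3_factor^ft$n_nh3[core$ti] *
    pfac * chg
  mx <- max(intensity)
  if (mx > 0) intensity <- intensity / mx
  intensity
}

#' @export
predict_spectrum.baseline_predictor <- function(predictor, p, grid = NULL) {
  core <- .theo_core(p)
  if (is.null(grid)) grid <- theoretical_spectrum(p)
  grid$intensity <- .baseline_intensity(predictor, p, core)
  grid
}

#' Spectral-library predictor
#'
#' Looks up predicted or experimental fragment intensities in a spectral
#' library table, keyed by (modified sequence, precursor charge). On a key
#' miss it returns NULL so the caller can decide a fallback; duplicate keys
#' keep the entry with the highest score (then first occurrence), with a
#' warning.
#'
#' @param entries Data frame with columns `modified_sequence`,
#'   `precursor_charge`, `fragment_type` (36-type label), `fragment_index`
#'   (cleavage index), `relative_intensity`, and optionally `score`.
#' @return Predictor object of class `library_predictor`.
#' @export
library_predictor <- function(entries) {
  req <- c("modified_sequence", "precursor_charge", "fragment_type",
           "fragment_index", "relative_intensity")
  missing_cols <- setdiff(req, names(entries))
  if (length(missing_cols))
    stop("library is missing column(s): ", paste(missing_cols, collapse = ", "))
  key <- paste(entries$modified_sequence, entries$precursor_charge, sep = "/")
  if (!is.null(entries$entry_id)) {
    eid <- entries$entry_id
  } else eid <- key
  # resolve duplicate (key, fragment) groups coming from distinct entries
  ids <- unique(data.frame(key = key, eid = eid,
                           score = if (is.null(entries$score)) 0 else entries$score,
                           stringsAsFactors = FALSE))
  dup_keys <- unique(ids$key[duplicated(ids$key)])
  if (length(dup_keys)) {
    warning("duplicate library keys; keeping highest-scoring entry: ",
            paste(utils::head(dup_keys, 5), collapse = ", "))
    keep <- unlist(lapply(split(ids, ids$key), function(g) {
      g$eid[order(-g$score)][1L]
    }))
    entries <- entries[eid %in% keep, , drop = FALSE]
    key <- key[eid %in% keep]
  }
  structure(list(entries = split(entries, key), name = "library",
                 deterministic = TRUE),
            class = "library_predictor")
}

#' @export
predict_spectrum.library_predictor <- function(predictor, p, grid = NULL) {
  key <- paste(format_modified_sequence(p), p$charge, sep = "/")
  hit <- predictor$entries[[key]]
  if (is.null(hit)) return(NULL)
  if (is.null(grid)) grid <- theoretical_spectrum(p)
  idx <- match(paste(grid$label, grid$cleavage),
               paste(hit$fragment_type, hit$fragment_index))
  grid$intensity <- ifelse(is.na(idx), 0, hit$relative_intensity[idx])
  grid
}
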