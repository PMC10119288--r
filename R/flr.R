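# Target-decoy FLR engine: score spectra against candidate sets, compute
# delta scores, rank, and estimate / evaluate the false localization rate.

score_candidate <- function(candidate, spectrum, predictor, params) {
  if (inherits(predictor, "baseline_predictor")) {
    core <- .theo_core(candidate)
    predv <- .baseline_intensity(predictor, candidate, core)
    tmz <- core$mz
  } else {
    grid <- theoretical_spectrum(candidate)
    pred <- predict_spectrum(predictor, candidate, grid = grid)
    if (is.null(pred)) return(NA_real_)   # library miss
    predv <- pred$intensity
    tmz <- grid$mz
  }
  expv <- match_peaks(tmz, spectrum, params)
  if (max(expv) <= 0) return(NA_real_)  # nothing matched
  if (params$transform == "normalized_log") {
    expv <- normalize_intensities(expv)
    predv <- normalize_intensities(predv)
  }
  na <- sqrt(sum(predv^2)); nb <- sqrt(sum(expv^2))
  if (na == 0 || nb == 0) return(0)
  sum(predv * expv) / (na * nb)
}

#' Score one spectrum against its candidate set
#'
#' Computes the cosine similarity between the experimental spectrum and the
#' predicted spectrum of every target and decoy candidate, reports the best
#' match (ties between a target and a decoy resolve to the decoy,
#' conservatively), and the delta score: best cosine minus the cosine of
#' the target isoform closest to the best (excluding the best itself when
#' the best is a target). A set whose best match leaves no other target
#' (should not occur for re-analyzable sets) gets delta equal to the best
#' cosine and is flagged.
#'
#' @param spectrum An [ms_spectrum].
#' @param cset A candidate set from [build_candidate_database()].
#' @param predictor A spectrum predictor.
#' @param params A [matching_params].
#' @param detail Attach the full per-candidate score table as attribute
#'   `"scores"` (default FALSE).
#' @return One-row data frame: `spectrum_id`, `peptidoform` (formatted),
#'   `is_decoy`, `cosine`, `delta`, `n_candidates`, `scorable`,
#'   `single_target`.
#' @export
score_spectrum <- function(spectrum, cset, predictor,
                           params = matching_params(), detail = FALSE) {
  cands <- c(cset$targets, cset$decoys)
  if (!length(cands)) stop("empty candidate set")
  is_decoy <- c(rep(FALSE, length(cset$targets)), rep(TRUE, length(cset$decoys)))
  cos <- vapply(cands, score_candidate, 0, spectrum = spectrum,
                predictor = predictor, params = params)
  if (all(is.na(cos)) || all(cos[!is.na(cos)] <= 0, na.rm = TRUE) ||
      max(cos, na.rm = TRUE) <= 0) {
    return(data.frame(spectrum_id = cset$spectrum_id, peptidoform = NA_character_,
                      is_decoy = NA, cosine = NA_real_, delta = NA_real_,
                      n_candidates = length(cands), scorable = FALSE,
                      single_target = FALSE, stringsAsFactors = FALSE))
  }
  cos[is.na(cos)] <- -Inf
  best_cos <- max(cos)
  tied <- which(cos == best_cos)
  best_i <- if (any(is_decoy[tied])) tied[is_decoy[tied]][1L] else tied[1L]
  target_cos <- cos[!is_decoy]
  if (!is_decoy[best_i]) {
    ti <- which(!is_decoy)
    target_cos <- cos[setdiff(ti, best_i)]
  }
  target_cos <- target_cos[is.finite(target_cos)]
  single <- length(target_cos) == 0L
  delta <- if (single) best_cos else best_cos - max(target_cos)
  out <- data.frame(spectrum_id = cset$spectrum_id,
                    peptidoform = format_modified_sequence(cands[[best_i]]),
                    is_decoy = is_decoy[best_i], cosine = best_cos,
                    delta = delta, n_candidates = length(cands),
                    scorable = TRUE, single_target = single,
                    stringsAsFactors = FALSE)
  if (detail)
    attr(out, "scores") <- data.frame(
      peptidoform = vapply(cands, format_modified_sequence, ""),
      cosine = ifelse(is.finite(cos), cos, NA_real_), is_decoy = is_decoy,
      stringsAsFactors = FALSE)
  out
}

#' Estimated false localization rate
#'
#' FLR_estimated = ((N_decoy + N_target) / N_decoy) * (D / (T + D)),
#' capped at 1, where N_decoy and N_target are the total decoy and target
#' counts in the candidate database and D, T the decoy and target hits
#' above the score threshold.
#'
#' @param n_decoy,n_target Global candidate counts (n_decoy > 0).
#' @param d,t Decoy and target hit counts above the threshold (d + t > 0).
#' @return Estimated FLR in the 0-1 range.
#' @examples
#' estimate_flr(100, 100, d = 1, t = 99)  # 0.02
#' @export
estimate_flr <- function(n_decoy, n_target, d, t) {
  if (n_decoy <= 0) stop("n_decoy must be positive")
  if (d + t <= 0) stop("no hits above threshold")
  min(1, (n_decoy + n_target) / n_decoy * d / (t + d))
}

#' Real (ground-truth) false localization rate
#'
#' FP / (TP + FP), where a hit is a true positive only when its full
#' modified sequence (phosphosites included) matches the ground truth for
#' its spectrum; decoy hits and mislocalized targets count as false
#' positives.
#'
#' @param psms Data frame with `spectrum_id`, `peptidoform`, `is_decoy`.
#' @param truth Data frame with `spectrum_id` and the true
#'   `modified_sequence`.
#' @return Real FLR in the 0-1 range.
#' @export
real_flr <- function(psms, truth) {
  tv <- truth$modified_sequence[match(psms$spectrum_id, truth$spectrum_id)]
  if (anyNA(tv)) stop("ground truth missing for some spectra")
  tp <- sum(!psms$is_decoy & psms$peptidoform == tv)
  fp <- nrow(psms) - tp
  fp / (tp + fp)
}

#' Delta-score sweep with cumulative FLR
#'
#' Ranks scored records by descending delta score and computes the
#' estimated FLR at every threshold; records with equal delta scores form
#' atomic tie groups (a threshold admits all or none of a group). When
#' ground truth is supplied the real FLR is computed alongside.
#'
#' @param psms Data frame of scored records ([score_spectrum()] rows);
#'   unscorable and single-target records are excluded with a message.
#' @param n_decoy,n_target Global candidate counts.
#' @param truth Optional ground-truth data frame (see [real_flr()]).
#' @return Data frame of class `flr_curve`, one row per tie group:
#'   `delta` (group threshold), `n_accepted`, `cum_target`, `cum_decoy`,
#'   `flr_estimated`, and `flr_real` when truth is given.
#' @export
flr_curve <- function(psms, n_decoy, n_target, truth = NULL) {
  drop <- !psms$scorable | psms$single_target
  if (any(drop)) {
    message("excluding ", sum(drop), " unscorable/single-target record(s)")
    psms <- psms[!drop, , drop = FALSE]
  }
  if (!nrow(psms)) stop("no scorable records")
  psms <- psms[order(-psms$delta), , drop = FALSE]
  thresholds <- unique(psms$delta)
  grp_end <- cumsum(tabulate(match(psms$delta, thresholds), nbins = length(thresholds)))
  cumD <- cumsum(psms$is_decoy)[grp_end]
  cumN <- grp_end
  cumT <- cumN - cumD
  est <- pmin(1, (n_decoy + n_target) / n_decoy * cumD / cumN)
  out <- data.frame(delta = thresholds, n_accepted = cumN,
                    cum_target = cumT, cum_decoy = cumD, flr_estimated = est)
  if (!is.null(truth)) {
    tv <- truth$modified_sequence[match(psms$spectrum_id, truth$spectrum_id)]
    correct <- !psms$is_decoy & psms$peptidoform == tv
    correct[is.na(correct)] <- FALSE
    cumTP <- cumsum(correct)[grp_end]
    out$flr_real <- (cumN - cumTP) / cumN
  }
  attr(out, "n_decoy") <- n_decoy
  attr(out, "n_target") <- n_target
  attr(out, "records") <- psms
  class(out) <- c("flr_curve", "data.frame")
  out
}

#' Delta-score threshold at a target estimated FLR
#'
#' Finds the largest accepted prefix of the ranked list whose estimated
#' FLR does not exceed `alpha`, honouring atomic tie groups.
#'
#' @param curve An [flr_curve()].
#' @param alpha Estimated-FLR ceiling (default 0.01).
#' @return List: `threshold` (minimal accepted delta score, NA when no
#'   prefix qualifies), `n_accepted`, `flr_estimated`, `flr_real` (when
#'   available), `accepted` (the accepted records).
#' @export
threshold_at_flr <- function(curve, alpha = 0.01) {
  ok <- which(curve$flr_estimated <= alpha)
  if (!length(ok)) {
    message("no threshold attains estimated FLR <= ", alpha)
    return(list(threshold = NA_real_, n_accepted = 0L, flr_estimated = NA_real_,
                flr_real = NA_real_, accepted = attr(curve, "records")[0, ]))
  }
  i <- max(ok)
  recs <- attr(curve, "records")
  list(threshold = curve$delta[i], n_accepted = curve$n_accepted[i],
       flr_estimated = curve$flr_estimated[i],
       flr_real = if ("flr_real" %in% names(curve)) curve$flr_real[i] else NA_real_,
       accepted = recs[recs$delta >= curve$delta[i], , drop = FALSE])
}

#' Estimated/real FLR of a curve at given delta-score thresholds
#'
#' @param curve An [flr_curve()].
#' @param thresholds Numeric vector of delta-score cutoffs.
#' @return Data frame with one row per threshold: `threshold`,
#'   `flr_estimated`, `flr_real` (NA when unavailable or when no record
#'   passes the cutoff).
#' @export
flr_at_thresholds <- function(curve, thresholds) {
  est <- real <- rep(NA_real_, length(thresholds))
  for (i in seq_along(thresholds)) {
    j <- which(curve$delta >= thresholds[i])
    if (length(j)) {
      j <- max(j)  # curve rows are delta-descending
      est[i] <- curve$flr_estimated[j]
      if ("flr_real" %in% names(curve)) real[i] <- curve$flr_real[j]
    }
  }
  data.frame(threshold = thresholds, flr_estimated = est, flr_real = real)
}

#' Half-width of the repeat-analysis 95% confidence interval
#'
#' half_width = coef * sqrt(sum((x_i - mean)^2) / (n (n - 1))). For n = 10
#' repeats the coefficient is the constant 2.26 (two-sided 95% t quantile
#' at 9 degrees of freedom); for other n it is derived from the t
#' distribution. A single valid value yields half-width 0.
#'
#' @param x Numeric vector of per-repeat measurements (NAs dropped).
#' @param conf Confidence level (default 0.95).
#' @return Non-negative half-width.
#' @export
ci_half_width <- function(x, conf = 0.95) {
  x <- x[!is.na(x)]
  n <- length(x)
  if (n <= 1L) return(0)
  coef <- if (n == 10L && conf == 0.95) 2.26
          else stats::qt(1 - (1 - conf) / 2, df = n - 1L)
  coef * sqrt(sum((x - mean(x))^2) / (n * (n - 1)))
}

#' Repeat an analysis over seeds and summarize with confidence intervals
#'
#' @param fun Function of a single integer seed returning a numeric vector
#'   (aligned across seeds, e.g. FLR at a fixed threshold grid).
#' @param seeds Integer vector of seeds (default 1:10).
#' @return Data frame with per-element `mean` and `half_width` (95% CI) and
#'   the per-seed values as columns.
#' @export
repeat_with_ci <- function(fun, seeds = 1:10) {
  vals <- sapply(seeds, fun)
  if (is.null(dim(vals))) vals <- matrix(vals, nrow = 1L)
  data.frame(mean = rowMeans(vals, na.rm = TRUE),
             half_width = apply(vals, 1L, ci_half_width))
}

#' Re-localize phosphosites and estimate the FLR for a dataset
#'
#' The full pipeline: build the candidate database from the search
#' identifications, score every re-analyzable spectrum against its targets
#' and decoys with the given predictor, rank by delta score and compute
#' the FLR curve.
#'
#' @param spectra List of [ms_spectrum] (e.g. from [read_mgf()]).
#' @param identifications Search-result data frame
#'   ([read_search_results()]).
#' @param predictor Spectrum predictor (default [baseline_predictor()]).
#' @param decoy_method 1 (residue exchange) or 2 (phosphate shift).
#' @param seed Integer seed for the decoy draws.
#' @param params [matching_params()].
#' @param truth Optional ground-truth data frame for real-FLR evaluation.
#' @param max_phospho Maximum supported phosphate count (default 2).
#' @return Object of class `flr_result`: list with `psms`, `curve`,
#'   `db` (candidate database), `n_unscorable`.
#' @export
flr_rescore <- function(spectra, identifications,
                        predictor = baseline_predictor(), decoy_method = 1L,
                        seed = NULL, params = matching_params(),
                        truth = NULL, max_phospho = 2L) {
  db <- build_candidate_database(identifications, method = decoy_method,
                                 seed = seed, max_phospho = max_phospho)
  by_id <- stats::setNames(spectra, vapply(spectra, `[[`, "", "spectrum_id"))
  rows <- vector("list", length(db$sets))
  for (i in seq_along(db$sets)) {
    cs <- db$sets[[i]]
    s <- by_id[[cs$spectrum_id]]
    if (is.null(s)) next
    rows[[i]] <- score_spectrum(s, cs, predictor, params)
  }
  psms <- do.call(rbind, rows)
  if (is.null(psms) || !nrow(psms)) stop("no spectra could be scored")
  curve <- suppressMessages(
    flr_curve(psms, db$n_decoy, db$n_target, truth = truth))
  structure(list(psms = psms, curve = curve, db = db,
                 n_unscorable = sum(!psms$scorable | psms$single_target)),
            class = "flr_result")
}

#' @export
print.flr_result <- function(x, ...) {
  cat("Phosphosite re-localization result\n")
  cat("  spectra scored:   ", nrow(x$psms), " (", x$n_unscorable,
      " unscorable)\n", sep = "")
  cat("  candidates:       ", x$db$n_target, " targets, ", x$db$n_decoy,
      " decoys (method ", x$db$method, ")\n", sep = "")
  at1 <- threshold_at_flr(x$curve, 0.01)
  if (!is.na(at1$threshold))
    cat(sprintf("  at 1%% est. FLR:   delta >= %.4f, %d PSMs accepted\n",
                at1$threshold, at1$n_accepted))
  invisible(x)
}

#' @export
summary.flr_result <- function(object, alphas = c(0.01, 0.05), ...) {
  cat("FLR thresholds:\n")
  for (a in alphas) {
    th <- threshold_at_flr(object$curve, a)
    cat(sprintf("  alpha %.2f: threshold %s, %d accepted, est. FLR %s, real FLR %s\n",
                a,
                ifelse(is.na(th$threshold), "NA", sprintf("%.4f", th$threshold)),
                th$n_accepted,
                ifelse(is.na(th$flr_estimated), "NA", sprintf("%.4f", th$flr_estimated)),
                ifelse(is.na(th$flr_real), "NA", sprintf("%.4f", th$flr_real))))
  }
  invisible(object)
}

#' Plot estimated against real FLR
#'
#' @param x An `flr_result` whose curve carries a real FLR (ground truth
#'   supplied), or an `flr_curve`.
#' @param ... Passed to [plot()].
#' @export
plot.flr_result <- function(x, ...) plot(x$curve, ...)

#' @export
plot.flr_curve <- function(x, ...) {
  if ("flr_real" %in% names(x)) {
    plot(x$flr_real, x$flr_estimated, type = "l",
         xlab = "real FLR", ylab = "estimated FLR", ...)
    graphics::abline(0, 1, lty = 2, col = "grey")
  } else {
    plot(x$delta, x$flr_estimated, type = "l",
         xlab = "delta-score threshold", ylab = "estimated FLR", ...)
  }
  invisible(x)
}
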