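# helpers building minimal scored-record tables for curve arithmetic
records <- function(deltas, decoy, ids = NULL, pep = NULL) {
  data.frame(spectrum_id = ids %||% paste0("s", seq_along(deltas)),
             peptidoform = pep %||% paste0("P", seq_along(deltas)),
             is_decoy = decoy, cosine = 0.9, delta = deltas,
             n_candidates = 4L, scorable = TRUE, single_target = FALSE,
             stringsAsFactors = FALSE)
}
`%||%` <- function(a, b) if (is.null(a)) b else a

test_that("the estimated FLR follows the adjusted decoy-fraction formula", {
  expect_equal(estimate_flr(100, 100, d = 1, t = 99), 0.02)
  expect_equal(estimate_flr(100, 100, d = 0, t = 50), 0)
  expect_equal(estimate_flr(200, 100, d = 2, t = 98), 0.03)
  expect_equal(estimate_flr(10, 10, d = 9, t = 1), 1)   # capped
  expect_error(estimate_flr(0, 10, 1, 1), "positive")
  expect_error(estimate_flr(10, 10, 0, 0), "no hits")
  # with equal database sizes the estimate reduces to 2D/(T+D)
  for (d in 0:5) expect_equal(estimate_flr(50, 50, d, 10 - d), min(1, 2 * d / 10))
})

test_that("the real FLR counts full-peptidoform matches only", {
  truth <- data.frame(spectrum_id = paste0("s", 1:100),
                      modified_sequence = paste0("P", 1:100))
  ps <- records(runif(100), decoy = rep(FALSE, 100))
  expect_equal(real_flr(ps, truth), 0)
  ps$peptidoform[1] <- "WRONG"
  expect_equal(real_flr(ps, truth), 0.01)
  ps$is_decoy[2:6] <- TRUE      # decoy hits are false positives
  expect_equal(real_flr(ps, truth), 0.06)
  ps2 <- records(runif(5), decoy = rep(TRUE, 5))
  expect_equal(real_flr(ps2, truth[1:5, ]), 1)
  expect_error(real_flr(records(0.5, FALSE, ids = "zzz"), truth),
               "missing")
})

test_that("delta scores follow the nearest-target definition", {
  set.seed(31)
  cfg <- sim_config(n_peptides = 25, seed = 31)
  sim <- simulate_dataset(cfg)
  db <- build_candidate_database(sim$ids, method = 1, seed = 31)
  pr <- baseline_predictor()
  for (cs in db$sets[1:10]) {
    s <- sim$spectra[[match(cs$spectrum_id, sim$ids$spectrum_id)]]
    rec <- score_spectrum(s, cs, pr, detail = TRUE)
    if (!rec$scorable) next
    sc <- attr(rec, "scores")
    sc <- sc[!is.na(sc$cosine), ]
    best <- max(sc$cosine)
    expect_equal(rec$cosine, best)
    others <- sc$cosine[!sc$is_decoy & !(sc$peptidoform == rec$peptidoform &
                                           sc$cosine == best)]
    expect_equal(rec$delta, best - max(others), tolerance = 1e-12)
    expect_gte(rec$delta, 0)
  }
})

test_that("best-cosine ties between target and decoy resolve to the decoy", {
  # a decoy identical in score arises when the spectrum matches nothing:
  # construct a two-candidate set with equal predicted vectors by using
  # a symmetric peptide where swap reproduces the same sequence
  p <- parse_modified_sequence("pSAAK")
  cs <- list(spectrum_id = "tie", engine_peptidoform = p,
             targets = list(p), decoys = list(p), decoy_parent = 1L,
             reanalyzable = TRUE)
  pred <- predict_spectrum(baseline_predictor(), p)
  s <- ms_spectrum("tie", pred$mz, pred$intensity + 1e-9,
                   precursor_mz = precursor_mz(p), precursor_charge = 2L)
  rec <- score_spectrum(s, cs, baseline_predictor())
  expect_true(rec$is_decoy)
})

test_that("the FLR curve sweeps delta thresholds with atomic tie groups", {
  # all targets: estimated FLR 0 everywhere
  ps <- records(c(0.5, 0.4, 0.3), decoy = rep(FALSE, 3))
  cv <- flr_curve(ps, n_decoy = 3, n_target = 3)
  expect_true(all(cv$flr_estimated == 0))

  # alternating target/decoy with equal database sizes: FLR at rank 2k is
  # 2 * k / 2k = 1 (capped)
  ps2 <- records(seq(1, 0.1, length.out = 10),
                 decoy = rep(c(FALSE, TRUE), 5))
  cv2 <- flr_curve(ps2, n_decoy = 10, n_target = 10)
  even <- cv2[cv2$n_accepted %% 2 == 0, ]
  expect_true(all(abs(even$flr_estimated - 1) < 1e-12))

  # tie group: equal deltas enter together
  ps3 <- records(c(0.5, 0.2, 0.2, 0.2, 0.1),
                 decoy = c(FALSE, FALSE, TRUE, FALSE, FALSE))
  cv3 <- flr_curve(ps3, n_decoy = 5, n_target = 5)
  expect_equal(cv3$n_accepted, c(1L, 4L, 5L))
  expect_equal(cv3$cum_decoy, c(0L, 1L, 1L))

  # unscorable records are excluded with a message
  ps4 <- rbind(ps, transform(records(0.9, FALSE, ids = "u1"), scorable = FALSE))
  expect_message(cv4 <- flr_curve(ps4, 3, 3), "excluding 1")
  expect_equal(sum(cv4$n_accepted == 3), 1L)
})

test_that("threshold selection takes the largest prefix within alpha", {
  ps <- records(c(0.5, 0.4, 0.3), decoy = c(FALSE, FALSE, TRUE))
  cv <- flr_curve(ps, n_decoy = 100, n_target = 100)
  # FLRs: 0, 0, 2/3*2 -> first two accepted at alpha 0.01
  th <- threshold_at_flr(cv, alpha = 0.01)
  expect_equal(th$n_accepted, 2L)
  expect_equal(th$threshold, 0.4)
  expect_equal(nrow(th$accepted), 2L)

  all_in <- threshold_at_flr(cv, alpha = 1.0)
  expect_equal(all_in$n_accepted, 3L)

  dec <- records(c(0.5, 0.4), decoy = c(TRUE, TRUE))
  cvd <- flr_curve(dec, n_decoy = 10, n_target = 10)
  expect_message(none <- threshold_at_flr(cvd, alpha = 0.01), "no threshold")
  expect_equal(none$n_accepted, 0L)
  expect_true(is.na(none$threshold))
})

test_that("confidence-interval arithmetic matches the repeat-analysis rule", {
  expect_equal(ci_half_width(rep(3.2, 10)), 0)
  expect_equal(ci_half_width(c(rep(0, 5), rep(2, 5))), 2.26 * sqrt(10 / 90),
               tolerance = 1e-6)
  expect_equal(ci_half_width(c(rep(0, 5), rep(2, 5))), 0.7535, tolerance = 1e-3)
  expect_equal(ci_half_width(5), 0)                   # single valid value
  expect_equal(ci_half_width(c(NA, NA, 5)), 0)
  # n != 10 falls back to the t quantile
  x <- c(1, 2, 3, 4)
  expect_equal(ci_half_width(x),
               qt(0.975, 3) * sqrt(sum((x - mean(x))^2) / (4 * 3)),
               tolerance = 1e-12)
})

test_that("the n = 10 coefficient equals the two-sided 95% t quantile at 9 df", {
  expect_equal(2.26, qt(0.975, df = 9), tolerance = 0.005)
})

test_that("repeat_with_ci aggregates per-threshold values over seeds", {
  fake <- function(seed) c(a = seed %% 2, b = 2)
  out <- repeat_with_ci(fake, seeds = 1:10)
  expect_equal(out$mean, c(0.5, 2))
  expect_equal(out$half_width[2], 0)
  expect_equal(out$half_width[1], ci_half_width(rep(c(1, 0), 5)))
})

test_that("full pipeline separates true sites and controls the FLR", {
  cfg <- sim_config(n_peptides = 120, seed = 77)
  sim <- simulate_dataset(cfg)
  res <- flr_rescore(sim$spectra, sim$ids, seed = 78, truth = sim$truth)
  expect_s3_class(res, "flr_result")
  expect_equal(nrow(res$psms), 120L)
  # estimated FLR at full acceptance is at least the FLR of the
  # high-confidence prefix on well-separated data
  cv <- res$curve
  expect_gte(cv$flr_estimated[nrow(cv)], cv$flr_estimated[1])
  # most identifications recover the true site
  th <- threshold_at_flr(cv, 0.01)
  tv <- sim$truth$modified_sequence[match(th$accepted$spectrum_id,
                                          sim$truth$spectrum_id)]
  recovery <- sum(!th$accepted$is_decoy & th$accepted$peptidoform == tv) / 120
  expect_gt(recovery, 0.85)
  expect_lte(th$flr_real, 0.05)
})
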