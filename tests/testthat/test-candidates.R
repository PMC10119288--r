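test_that("isoform enumeration covers all site subsets", {
  p <- parse_modified_sequence("pSTLVLHDLLK")
  iso <- enumerate_isoforms(p)
  expect_length(iso, 2L)   # candidate sites S1 and T2
  expect_setequal(vapply(iso, format_modified_sequence, ""),
                  c("S[Phospho]TLVLHDLLK", "ST[Phospho]LVLHDLLK"))

  one <- enumerate_isoforms(parse_modified_sequence("pSAK"))
  expect_length(one, 1L)

  di <- parse_modified_sequence("S[Phospho]AS[Phospho]TYGK", charge = 2)
  expect_length(enumerate_isoforms(di), choose(4, 2))
})

test_that("isoform count equals C(c, m) against brute-force enumeration", {
  # build peptides with c candidate sites spread among alanines
  for (c_sites in 2:8) {
    for (m in 1:min(c_sites, 3)) {
      seqc <- paste(c(rep(c("S", "A"), c_sites), "K"), collapse = "")
      sty <- which(strsplit(seqc, "")[[1]] == "S")
      p <- peptidoform(seqc, data.frame(pos = sty[seq_len(m)], name = "Phospho"))
      iso <- enumerate_isoforms(p)
      expect_length(iso, choose(c_sites, m))
      # brute force: formatted strings are exactly the site subsets
      combos <- utils::combn(sty, m, simplify = FALSE)
      want <- vapply(combos, function(ss)
        format_modified_sequence(peptidoform(seqc,
          data.frame(pos = ss, name = "Phospho"))), "")
      expect_setequal(vapply(iso, format_modified_sequence, ""), want)
    }
  }
})

test_that("method-1 decoys swap the phospho residue, preserving composition", {
  p <- parse_modified_sequence("pSTLVLHDLLK")
  set.seed(7)
  d <- decoy_method1(p)
  expect_length(d, 1L)
  dec <- d[[1]]
  # permutation of the residue multiset, different string
  expect_equal(sort(strsplit(dec$sequence, "")[[1]]),
               sort(strsplit(p$sequence, "")[[1]]))
  expect_false(dec$sequence == p$sequence)
  # phosphate travelled with its serine
  php <- phospho_positions(dec)
  expect_equal(substr(dec$sequence, php, php), "S")
  expect_equal(precursor_mz(dec), precursor_mz(p), tolerance = 1e-12)
})

test_that("a doubly phosphorylated target yields exactly two decoys", {
  p <- parse_modified_sequence("S[Phospho]AS[Phospho]TYGLK", charge = 2)
  set.seed(8)
  expect_length(decoy_method1(p), 2L)
  expect_length(decoy_method2(p), 2L)
})

test_that("decoy generation fails without a non-candidate residue", {
  p <- peptidoform("SSTY", data.frame(pos = 1, name = "Phospho"))
  expect_error(decoy_method1(p), "no non-candidate residue")
  expect_error(decoy_method2(p), "no unmodified non-candidate residue")
})

test_that("method-2 decoys keep the sequence and move the phosphate", {
  p <- parse_modified_sequence("pSTLVLHDLLK")
  set.seed(9)
  d <- decoy_method2(p)[[1]]
  expect_identical(d$sequence, p$sequence)
  php <- phosFLR:::phospho_positions(d)
  expect_false(substr(d$sequence, php, php) %in% c("S", "T", "Y"))
  expect_equal(precursor_mz(d), precursor_mz(p), tolerance = 1e-12)
})

test_that("both decoy methods are isobaric on random targets", {
  set.seed(10)
  for (i in 1:200) {
    nph <- sample(1:2, 1)
    p <- random_phosphopeptide(nph = nph)
    for (d in c(decoy_method1(p), decoy_method2(p))) {
      expect_lt(abs(precursor_mz(d) - precursor_mz(p)), 1e-6)
    }
  }
})

test_that("method-1 swaps carry stranded modifications with their residue", {
  # oxidized methionine at the swap position must travel to keep chemistry
  p <- parse_modified_sequence("S[Phospho]AM[Oxidation]K")
  set.seed(11)
  found_m_swap <- FALSE
  for (i in 1:50) {
    d <- decoy_method1(p)[[1]]
    mpos <- d$mods$pos[d$mods$name == "Oxidation"]
    expect_equal(substr(d$sequence, mpos, mpos), "M")
    if (phosFLR:::phospho_positions(d) == 3L) found_m_swap <- TRUE
  }
  expect_true(found_m_swap)
})

test_that("candidate database counts targets and decoys globally", {
  ids <- data.frame(spectrum_id = "s1", sequence = "STLVLHDLLK",
                    modified_sequence = "pSTLVLHDLLK", charge = 2,
                    localization_probability = 0.6)
  db <- build_candidate_database(ids, method = 1, seed = 3)
  expect_equal(db$n_target, 2L)
  expect_equal(db$n_decoy, 2L)
  expect_length(db$sets, 1L)
  expect_equal(db$sets[[1]]$decoy_parent, c(1L, 2L))
})

test_that("non-reanalyzable peptides go to the pass-through list", {
  ids <- data.frame(spectrum_id = c("s1", "s2"),
                    modified_sequence = c("pSAK", "pSTAK"), charge = 2,
                    localization_probability = 1)
  db <- build_candidate_database(ids, method = 1, seed = 3)
  expect_length(db$sets, 1L)
  expect_length(db$passthrough, 1L)
  expect_equal(db$passthrough[[1]]$spectrum_id, "s1")

  only <- build_candidate_database(ids[1, ], method = 1, seed = 3)
  expect_length(only$sets, 0L)
  expect_length(only$passthrough, 1L)
})

test_that("peptides beyond the phosphate cap are dropped with a message", {
  ids <- data.frame(spectrum_id = c("s1", "s2"),
                    modified_sequence = c("S[Phospho]T[Phospho]S[Phospho]ATYAK",
                                          "pSTAK"),
                    charge = 2, localization_probability = 1)
  expect_message(db <- build_candidate_database(ids, method = 1, seed = 3),
                 "dropped 1")
  expect_equal(db$n_dropped, 1L)
  expect_length(db$sets, 1L)
})

test_that("the candidate database is reproducible from its seed", {
  ids <- data.frame(spectrum_id = paste0("s", 1:5),
                    modified_sequence = c("pSTLVLHDLLK", "pSTAYK", "pTGSAVLK",
                                          "S[Phospho]AS[Phospho]TYGLK", "pYASTLK"),
                    charge = 2, localization_probability = 1)
  fmt <- function(db) lapply(db$sets, function(s)
    vapply(s$decoys, format_modified_sequence, ""))
  a <- build_candidate_database(ids, method = 1, seed = 99)
  b <- build_candidate_database(ids, method = 1, seed = 99)
  c2 <- build_candidate_database(ids, method = 1, seed = 100)
  expect_identical(fmt(a), fmt(b))
  expect_false(identical(fmt(a), fmt(c2)))
})

test_that("malformed rows are reported and an empty database errors", {
  ids <- data.frame(spectrum_id = c("s1", "s2"),
                    modified_sequence = c("pSTAZK", "PEPTIDEK"), charge = 2,
                    localization_probability = 1)
  expect_error(suppressWarnings(build_candidate_database(ids, method = 1)),
               "empty candidate database")
  ids2 <- rbind(ids, data.frame(spectrum_id = "s3",
                                modified_sequence = "pSTAK", charge = 2,
                                localization_probability = 1))
  expect_warning(build_candidate_database(ids2, method = 1, seed = 1),
                 "skipped 2")
})
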