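Package: phosFLR
Title: Target-Decoy False Localization Rate Control for Phosphoproteomics
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for controlling the false localization rate (FLR) of
    phosphorylation sites identified by tandem mass spectrometry. Builds
    per-spectrum candidate databases of phosphopeptide positional isoforms
    and isobaric decoys, annotates the 36 b/y fragment-peak types with
    phosphoric-acid, water and ammonia neutral losses, matches predicted
    against experimental spectra by cosine similarity with ppm tolerance,
    ranks identifications by delta score, and estimates the FLR from decoy
    hits. Includes a deterministic rule-based spectrum predictor, spectral
    library construction in three modes for data-independent acquisition,
    a Mascot generic format (MGF) reader/writer, and a ground-truthed
    synthetic phosphoproteome simulator for validation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports: stats, utils, graphics
Suggests: testthat (>= 3.0.0), jsonlite, withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
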