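---
title: "Target-decoy control of the phosphosite false localization rate"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Target-decoy control of the phosphosite false localization rate}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(phosFLR)
```

## The problem

Database search engines identify phosphopeptide *sequences* with a
controlled false discovery rate, but placing the phosphate on the right
residue is a separate, harder problem. Two positional isoforms of the same
peptide — same sequence, same number of phosphates, different sites — are
isobaric, and distinguishing them requires observing *site-determining
fragment ions*, which are frequently absent from tandem mass spectra. The
fraction of accepted identifications whose site is wrong is the **false
localization rate (FLR)**, and unlike the FDR it is not controlled by the
search engine.

phosFLR controls the FLR with a target-decoy strategy at the level of
spectral matching. For each identified phosphopeptide spectrum it builds a
candidate set containing every positional isoform (the *targets*) and, for
each target, deliberately wrong candidates (*decoys*) whose acceptance
rate traces the rate of false localizations. Each candidate's predicted
MS/MS spectrum is compared with the experimental spectrum by cosine
similarity; the best-scoring candidate is reported, identifications are
ranked by a delta score, and the FLR of any acceptance threshold is
estimated from the decoy hits above it.

## Candidate targets and decoys

Given a search-engine identification with $m$ phosphates and $c$ candidate
sites (S/T/Y residues), the target list is all $\binom{c}{m}$ positional
isoforms. Spectra with $c = m$ admit no alternative site and are passed
through unanalyzed; only spectra with $c > m$ are re-analyzed. Peptides
with more than two phosphates are excluded by default
(`max_phospho = 2`), as higher phospho-forms are rare.

Two decoy constructions are provided, one decoy per target per phosphate:

* **Method 1 (residue exchange, default)** — the phosphorylated residue
  and a uniformly chosen non-candidate (non-S/T/Y) residue swap positions,
  the phosphate travelling with its residue. The decoy is a permutation of
  the target's residues, hence strictly isobaric, and its phosphate still
  sits on a canonical residue.
* **Method 2 (phosphate shift)** — the sequence is untouched and the
  phosphate moves to a uniformly chosen non-candidate residue, producing a
  chemically non-canonical (e.g. phospho-leucine) but isobaric decoy.

A doubly phosphorylated target yields two decoys, each exchanging a single
phosphorylated residue. When a random draw reproduces an existing target
or decoy, it is redrawn up to the number of available positions and then
accepted with a warning; on short peptides collisions are otherwise
unavoidable. Non-phospho modifications keep their residues: a swap that
would strand an oxidation on a non-methionine moves the modification with
its residue instead. Method 2 never places the phosphate on a position
already carrying another modification. These collision and modification
policies are our own choices; alternatives (e.g. emitting colliding decoys
unchecked) would bias the decoy count on short peptides.

## Fragment annotation

Every candidate's theoretical spectrum enumerates 36 fragment-peak types:
b and y series, fragment charges 1 and 2, and nine neutral-loss classes —
none, $-\mathrm{NH_3}$, $-\mathrm{H_2O}$, and the phosphoric-acid classes
$-\mathrm{H_3PO_4}$, $-\mathrm{NH_3{-}H_3PO_4}$,
$-\mathrm{H_2O{-}H_3PO_4}$, $-2\mathrm{H_3PO_4}$,
$-\mathrm{NH_3{-}2H_3PO_4}$, $-\mathrm{H_2O{-}2H_3PO_4}$ — in a fixed
order so intensity vectors are comparable across sources. Masses are
monoisotopic throughout (proton 1.007276 Da, water 18.010565,
ammonia 17.026549, phosphoric acid 97.976896).

Two gating choices matter:

* A phosphoric-acid loss is emitted only when the fragment actually
  contains at least as many phosphates as the class removes. Emitting
  phospho losses from phosphate-free fragments would create physically
  impossible peaks, and would do so asymmetrically between isoforms.
  Decoy phosphates on non-canonical residues are treated exactly like
  S/T phosphates, keeping target and decoy annotation symmetric.
* Water/ammonia losses are emitted for every fragment without
  residue-composition gating — a deliberate simplification; composition
  rules vary across instruments and the symmetric treatment is what the
  FLR machinery needs.

b1 ions are emitted: for N-terminal site ambiguity (e.g. S1 vs T2) the b1
ion is precisely the site-determining ion.

## Spectral matching and the delta score

Experimental spectra are read from Mascot generic format (MGF).
Similarity is computed on the theoretical grid: for each feasible
theoretical ion, the closest experimental peak within 25 ppm (default)
supplies its intensity, missing ions are set to 0, and the cosine between
this vector and the predicted intensities is the candidate's score. An
experimental peak may serve several theoretical ions; ties resolve by
smallest ppm error. Unannotated experimental peaks are ignored — the
predicted spectrum only exists on the 36-type grid, so that is where the
comparison lives.

Scoring uses raw (max-normalized) intensities by default. The
$\log_2(x+1)$ transform of 0–1-normalized intensities is available via
`matching_params(transform = "normalized_log")` for workflows that train
or calibrate predictors on log intensities, but is not applied during
scoring unless requested.

The reported identification is the candidate with the highest cosine; a
tie between a target and a decoy resolves to the decoy (conservative).
The **delta score** is the best cosine minus the cosine of the target
isoform closest to the best (excluding the best itself when the best is a
target). Large deltas mean the site assignment is unambiguous.

## FLR estimation

Ranking all records by delta score, for a threshold admitting $T$ target
and $D$ decoy hits,

$$\widehat{\mathrm{FLR}} \;=\; \frac{N_\mathrm{decoy} + N_\mathrm{target}}
{N_\mathrm{decoy}} \cdot \frac{D}{T + D},$$

where $N_\mathrm{target}$ and $N_\mathrm{decoy}$ are the global candidate
counts in the database. The prefactor corrects for the database
composition: a false localization lands on a decoy with probability
$N_\mathrm{decoy}/(N_\mathrm{decoy}+N_\mathrm{target})$, so observed decoy
hits undercount false hits by exactly that factor. The estimate is capped
at 1 (values above 1 are meaningless; the cap is our choice). Records with
equal delta scores form atomic tie groups — a threshold admits all or none
of a group — keeping threshold semantics well defined. Counting
$N_\mathrm{target}$/$N_\mathrm{decoy}$ globally follows the database
framing of the estimator; the counts are attributes of the candidate
database, so per-spectrum variants can be computed by the user if wanted.

With ground truth (simulation), the real FLR is
$\mathrm{FP}/(\mathrm{TP}+\mathrm{FP})$, where a hit is a true positive
only when the full modified sequence, sites included, matches the truth;
decoy hits and mislocalized targets are false positives.

Repeat analyses (decoy generation is stochastic) are summarized as
$\bar{x} \pm 2.26\sqrt{\sum_i (x_i-\bar{x})^2 / (n(n-1))}$ for $n = 10$
repeats, 2.26 being the two-sided 95% t quantile at 9 degrees of freedom;
for other $n$ the coefficient generalizes to `qt(0.975, n - 1)`, and a
single valid value yields a zero-width interval.

## The predictor contract

The scoring machinery is predictor-agnostic: anything implementing
`predict_spectrum()` — returning non-negative intensities on the feasible
fragment grid — can drive it. Two implementations ship:

* `baseline_predictor()` — a fully deterministic rule-based model:
  unimodal b/y intensity profile over cleavage index (peaking
  mid-sequence, width 0.35 of the peptide length), y ions 1.0 vs b ions
  0.7, neutral-loss peaks as fixed fractions of the parent ion (water and
  ammonia 0.2; phosphoric acid 0.5 from phospho-S/T and 0.1 from
  phospho-Y, reflecting the lability difference; combined losses
  multiply), doubly charged fragments at 0.3 of singly charged, spectrum
  renormalized to maximum 1. All constants are arguments.
* `library_predictor()` — exact-key lookup in a spectral-library table;
  a key miss is signalled (NULL), never silently zeroed, and duplicate
  keys resolve by score then input order with a warning. This is the
  adapter for externally predicted libraries, including ones produced by
  learned intensity models.

A learned intensity predictor would sharpen the cosine contrast between
isoforms, but the FLR machinery itself — candidates, decoys, delta
ranking, estimation — is independent of how the intensities are produced.

## DIA spectral libraries

From FLR-accepted identifications, `build_library()` produces a flat
one-fragment-per-row TSV in three modes: **predicted** (all intensities
from the predictor), **hybrid** (predicted intensities only for entries
whose site assignment changed relative to the input engine, experimental
otherwise), and **relocalized** (experimental intensities annotated on
the fragment grid, with the re-localized identifications). Retention
times are always experimental. Entries with fewer than 4 nonzero
fragments are dropped (configurable; standard library hygiene), and
duplicate peptidoform/charge keys keep the highest-cosine PSM.

## The simulator: what it emulates and what it does not

`simulate_dataset()` generates tryptic-like phosphopeptides (C-terminal
K/R, no internal K/R, length 8–16, S/T/Y at density 0.25 split 40/40/20,
each peptide guaranteed more candidate sites than phosphates), phosphate
counts 90% mono / 10% di, charges 2+ (70%) and 3+ (30%). Spectra start
from the predictor's spectrum of the *true* isoform, then: each peak is
dropped with probability 0.3, surviving intensities are multiplied by
log-normal noise ($\sigma = 0.5$), m/z values are jittered by
$\mathcal{N}(0, 5\,\mathrm{ppm})$, and 12 contaminant peaks are added
uniformly at up to 0.2 of the base peak. A search-result table reports a
wrong isoform for 10% of spectra, mimicking imperfect upstream
localization.

The noise level was chosen to emulate routine orbitrap HCD data:
substantial fragment dropout is the norm, and it is exactly what makes
site localization ambiguous. Milder settings (e.g. 10% dropout) make the
simulation degenerate — essentially every site is recovered and neither
decoys nor false hits occur, which validates nothing. At the chosen
defaults roughly 1–2% of spectra are confusable, producing comparably
sized decoy-hit and false-hit populations while still recovering the
large majority of true sites at 1% estimated FLR.

By default the simulator uses the *same* predictor as the scorer — the
favorable case in which predicted and "observed" intensity profiles agree
up to noise. Passing a differently parameterized `baseline_predictor()`
to `simulate_dataset()` emulates predictor/experiment mismatch. What
passing tests on this simulator do **not** show: robustness to real
instrument artifacts (co-isolation chimeras, isotope interference,
profile-mode effects), to retention-time-dependent effects, or to a badly
mis-specified intensity model; those require real data and a trained
predictor.

## Numerical choices and edge cases

* Peak matching: closest peak within tolerance, not most intense —
  deterministic and standard.
* All-zero matched vectors: the candidate scores `NA`; if no candidate of
  a spectrum matches anything, the record is flagged unscorable and
  excluded from ranking with a message.
* A candidate set with a single target cannot have a delta score in the
  usual sense; defensively, delta is the best cosine itself and the
  record is flagged and excluded (the re-analyzability filter should
  prevent this).
* Isobarity of decoys is exact by construction (composition is
  preserved), and verified to 1e-6 Th in the tests.
* Sequence length is capped below 512 residues; positions are 1-based
  with 0 reserved for the protein N-terminus (acetyl).
* Cysteine is never implicitly carbamidomethylated; fixed modifications
  must be explicit in the input.

## Problem sizes used in validation

The packaged test suite exercises: mass arithmetic against an independent
elemental-composition oracle over 1000 random peptidoforms (tolerance
1e-4 Th); decoy isobarity over 1000 random targets (1e-6 Th); isoform
combinatorics up to 8 candidate sites; FLR calibration on ten simulated
runs of 500 peptides (mean estimated vs mean real FLR within 0.05
absolute wherever real FLR ≤ 0.10); and the decoy-trace property
(two-sample Kolmogorov–Smirnov between decoy-hit and known-false-hit
delta distributions, α = 0.01) on a 2000-peptide run. These sizes give
stable statistics for the properties checked while keeping the suite
quick to run.

## A worked run

```{r, eval = FALSE}
cfg <- sim_config(n_peptides = 200, seed = 42)
sim <- simulate_dataset(cfg)
res <- flr_rescore(sim$spectra, sim$ids, seed = 43, truth = sim$truth)
print(res)
summary(res)
plot(res)   # estimated vs real FLR

th <- threshold_at_flr(res$curve, alpha = 0.01)
lib <- build_library(th$accepted, sim$spectra, mode = "predicted")
write_speclib(lib, "phospho_library.tsv")
```

## Known limitations

* The shipped baseline predictor is a rule-based surrogate; absolute
  cosine values are not comparable to those of a trained intensity model,
  though the FLR machinery is unaffected.
* Only b/y ions with the nine loss classes are modelled — no a/c/x/z
  ions, internal fragments, immonium ions, or isotope envelopes.
* MGF is the only spectrum format read; convert mzML upstream.
* Peptide-sequence FDR is assumed controlled by the upstream search
  engine; phosFLR only re-localizes phosphates on identified sequences.
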