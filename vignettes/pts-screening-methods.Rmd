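---
title: "Screening proteomes for peroxisomal targeting signals: models and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Screening proteomes for peroxisomal targeting signals}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ptsscreen)
```

## The screening problem

Most peroxisomal matrix proteins are imported by one of two receptor systems:
PEX5 recognises the C-terminal **PTS1** — an SKL-type tripeptide whose
efficiency is modulated by the preceding residues, so predictors evaluate the
last 12 residues — and PEX7 recognises the N-terminal **PTS2** nonapeptide.
A naive tripeptide scan over a vertebrate proteome returns thousands of hits,
most of them membrane, secretory or cytosolic proteins whose C-terminus is
never presented to PEX5. A practical screen therefore interleaves motif
matching with exclusion filters:

1. a **broad consensus gate** on the C-terminal tripeptide,
   `[ASCNPHTG]-[RKHQNSL]-[LMIVF]`, deliberately wide so weak and
   non-canonical signals survive to the scoring stage;
2. a **transmembrane filter**: proteins with predicted membrane helices are
   removed unless the helix signal is confined to the N-terminal 60 residues
   (i.e. is plausibly a cleavable signal peptide);
3. a **secretory/ER exclusion**: proteins routed into the ER never meet the
   peroxisomal import machinery, so signal-peptide and KDEL-type
   retention-motif carriers are removed;
4. a **position-specific score** over the C-terminal 12-mer that classifies
   survivors as *targeted* (score > 0), *twilight* (−10 < score ≤ 0; a weak
   but not excluded signal) or rejected (≤ −10, treated as "no predictor
   hit").

`run_cascade()` applies these stages in exactly this order and accounts for
every input protein with a single fate; PTS2 hits and a crude mitochondrial
presequence propensity are recorded as advisory annotations for everything
that passes the consensus gate, but never drop a record — in the original
screening design those checks were post-hoc validation, not filters.

## The PTS1 scoring model

`pts1_model()` fits an additive log-odds position-specific scoring matrix
(PSSM) on aligned C-terminal 12-mers. For position $p$ and residue $a$,

$$ w_{p,a} \;=\; \log_2 \frac{c_p(a) + \kappa\, b(a)}
  {\sum_r \left(c_p(r) + \kappa\, b(r)\right)} \;-\; \log_2 b(a), $$

with observed counts $c_p$, background frequencies $b$ (default uniform
1/20) and pseudocount $\kappa$ (default 1). A dodecamer's raw score is the
sum of its twelve weights; the reported score subtracts a calibration
offset. The padding letter `X` — and `U`, which is retained in sequences but
carries no trained column — scores exactly 0 at every position, so short
sequences are penalised only by missing evidence, never actively.

The PSSM form itself is a design choice: the thresholds (0 and −10) and the
12-residue window are fixed by the screening convention this package
implements, but the scoring function behind them is ours. An additive PSSM
was chosen over richer models because the curated training material is small
(tens of sequences), and because additivity gives exact, testable score
arithmetic: substituting one residue changes the score by precisely the
weight difference at that position.

### Offset calibration

The twilight band only means something once the score scale is anchored.
The offset is calibrated from classification constraints — dodecamers with a
required category. A TARGETED constraint bounds the offset from above
(`offset < raw`), a TWILIGHT constraint brackets it
(`raw ≤ offset < raw + 10`), a REJECTED constraint bounds it from below.
The fitted offset is the **midpoint of the feasible interval**, which is
deterministic and keeps both constraint margins equal; when the constraints
bound only one side, the offset is placed 5 units (half the twilight
bandwidth) inside the bound, and with no constraints at all it falls back to
the 5th percentile of the training raw scores (so roughly 95% of the
training material scores as targeted). An infeasible constraint set is a
loud construction error, never silently relaxed.

The bundled model is calibrated on three experimentally characterised
reporter C-termini: the Cdc5l 12-mer (clear peroxisomal targeting) is
constrained TARGETED, and the Meox2a and Kctd5a 12-mers (no or weak,
cytosol-dominated targeting) are constrained TWILIGHT:

```{r calibration}
m <- pts1_default_model()
m
predict(m, pts1_reporters()$insert)
```

### The bundled training set

The curated zebrafish training file ships one C-terminal 12-mer per curated
peroxisomal matrix protein, covering the tripeptide spectrum from canonical
(SKL, AKL, ARL, SRL) to weak (TKL, SRV, SKV, HKL, SKM, ANM, ...). Only the
tripeptides are curated observations; the nine upstream context residues are
*synthetic* — constructed once from a composition-weighted draw with a
guaranteed minimum residue diversity per position, then frozen — because the
curated sources print the motifs, not their full C-termini. The file
documents this. One consequence to keep in mind: position 1–9 weights
reflect that synthetic context pool, not biological context preferences, and
the model's discrimination rests mainly on positions 10–12 plus calibration.
Curated motifs that fall outside the broad consensus (QKL, FRL, SML) are
excluded — the gate runs before the scorer, so the scorer never sees them.

## Topology and sorting heuristics

The membrane and secretory stages are *stand-ins with explicit contracts*,
not re-implementations of the HMM-based predictors used interactively in the
original screen. They are deterministic, fast and fully specified:

* **`tm_profile()`** — Kyte–Doolittle hydropathy averaged over a centred
  19-residue window (truncated at the termini); windowed values ≥ 1.6 mark
  candidate helix residues; only runs of ≥ 15 such residues count as
  transmembrane segments. ExpAA is the summed propensity, ExpAA-60 its
  restriction to the first 60 residues. Window 19, threshold 1.6 and minimum
  run 15 are the standard textbook settings for single-helix detection and
  are all exposed in `cascade_config()`.
* **`apply_tm_rule()`** — keep when no helix, or when
  `exp_aa_60/exp_aa ≥ 0.9`. The retention sentence this rule implements is
  grammatically ambiguous about the ratio's direction; it is resolved here
  as "helix signal concentrated in the first 60 residues ⇒ keep", because
  the stated intent is to exempt proteins whose only hydrophobic stretch is
  a signal peptide. Inside/outside topology labels carry no information for
  this decision and are collapsed to `NONE`.
* **`detect_secretory_signal()`** — a secretory call requires all three
  classical signal-peptide elements (initiator Met; a basic n-region residue
  in positions 1–5; an h-region run of ≥ 8 residues with hydropathy ≥ 1.6
  within residues 6–30). The conjunction is deliberately precision-oriented:
  this stage *deletes* candidates, and a false ER call silently removes a
  true peroxisomal protein. ER retention is the C-terminal
  `[KRHQSA]-[DE]-E-L` motif.
* **`mts_score()`** — net basic charge over the first 25 residues, scaled
  to [0, 1]. Advisory only.

The PTS2 matcher is a set-membership scan of the first 40 residues (PTS2 is
N-terminal and often cleaved) against nine per-position residue sets. The
shipped pattern is the classical `R/K - L/V/I - x - x - L/V/I/H - L/S/G/A -
x - H/Q - L/A/F` consensus widened at positions 2, 5, 6 and 9 so that the
experimentally tested Uraha nonapeptide `RLQHIRGHI` is admitted; the matcher
reports candidates and does not adjudicate their functionality (the Uraha
signal, notably, did not direct peroxisomal import in cells). PTS2 matching
is qualitative — no score is attached.

## The synthetic proteome generator

`generate_proteome()` emits labelled records of six classes: canonical and
twilight PTS1 proteins (curated 12-mer planted flush with the C-terminus and
*verified* against the bundled model's category before emission, with up to
100 resamples), PTS2 proteins (pattern-satisfying nonapeptide inside the
first 40 residues, non-matching C-terminus), membrane decoys (PTS1-like
C-terminus plus a 23-residue L/I/V core planted at residue ≥ 70, where the
first-60 ratio rule must reject it; a variant flag plants it at residue 10
to exercise the signal-peptide exemption), secretory decoys (PTS1-like
C-terminus behind a constructed signal peptide), and background records
whose C-terminal tripeptide is re-drawn until it fails the consensus.
Background residues are i.i.d. draws from a fixed, shipped vertebrate-average
composition — reproducibility is preferred over compositional realism, and
the table is replaceable.

Default class sizes (100 canonical / 50 twilight / 50 PTS2 / 100 membrane
decoys / 100 secretory decoys / 600 background; lengths uniform on
120–600) keep the default test proteome at 1,000 records — large enough for
stable per-class rates, small enough that the whole suite runs in seconds.
Generation is deterministic under the spec seed and restores the caller's
RNG state.

What passing on synthetic data does **not** show: real proteomes have
correlated residue composition, isoforms, tail-anchored membrane proteins
with single C-terminal helices shorter than 15 hydrophobic residues, signal
anchors, and PTS1 contexts shaped by selection. The synthetic classes probe
each cascade stage's contract, not the biological error rate of the
heuristics; proteome-scale survivor counts from the original screen are
deliberately not an evaluation target, since they depend on an unversioned
proteome snapshot and on third-party predictor binaries.

## Numerical and degenerate-input conventions

* Sequences shorter than 12 are left-padded with `X` for scoring; shorter
  than 15 are never called secretory; shorter than 25 get `mts_score` 0;
  the KDEL-type motif needs ≥ 4 residues.
* Terminal `*` (translated ORF convention) is stripped on input; internal
  `*` or any letter outside the 20 standard residues plus `X/U/B/Z` is a
  validation error naming record and position.
* The consensus gate treats `X`/`U` in the tripeptide as non-matching: an
  undetermined C-terminus is not evidence of a signal.
* Stage order is fixed; `REJECTED` (≤ −10) at the scoring stage maps to the
  "no predictor hit" fate, since the twilight band is the only
  sub-threshold band the screen retains.
* All heuristics are deterministic; the only randomness in the package is
  the generator's seeded RNG.
* Ortholog pair categories: both-sides-identical status is CONSERVED —
  including conserved *absence* of a PTS1, which keeps the category set
  closed without inventing a separate label.

## Worked example

```{r cascade}
prot <- generate_proteome(synthetic_spec(
  n_canonical_pts1 = 20, n_twilight_pts1 = 10, n_pts2 = 10,
  n_tm_pts1_decoy = 15, n_er_pts1_decoy = 15, n_background = 60,
  seed = 42))
report <- run_cascade(prot$records)
report
table(planted = prot$truth$label, fate = report$table$final_fate)
```

## Known limitations

* The hydropathy heuristics miss helices shorter than 15 residues and
  marginally hydrophobic helices; tail-anchored proteins in particular can
  pass the membrane filter.
* The secretory detector requires the full Met/n-region/h-region triad, so
  uncleaved signal anchors and atypical signal peptides pass.
* The PTS1 model shares one matrix across species; species-specific models
  can be supplied to `compare_orthologs()` but are not bundled.
* Consensus-violating non-canonical motifs (QKL, FRL, SML) never reach the
  scorer by construction; proteins carrying them must be curated by hand.
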