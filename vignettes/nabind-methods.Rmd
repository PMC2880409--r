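---
title: "Predicting DNA- and RNA-binding residues from sequence features"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Predicting DNA- and RNA-binding residues from sequence features}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(nabind)
```

## The problem

Protein–DNA and protein–RNA interactions are mediated by a minority of
residues at the interaction interface. When the structure of a complex is
known, those residues can be read off directly: a residue is a binding site
when any of its side-chain or backbone heavy atoms lies within 3.5 Å of any
atom of the nucleic-acid partner. Structures are scarce, however, so the
practical task is to predict binding residues from sequence alone.

`nabind` frames this as residue-level binary classification. Each residue is
described by a sliding window of `w = 11` consecutive residues with the
target in the middle; the five sequence neighbours on each side provide
local context. A sequence of `n` residues yields `n − w + 1` training
instances, each labelled `+1` (binding) or `−1` (non-binding) by the target
residue's status. Binding residues are rare — roughly 15% of residues in
structure-derived datasets — so evaluation leans on class-balanced measures
rather than raw accuracy.

## Features

Three per-residue feature groups are available, alone or combined:

* **Biochemical features (`hkm`)** — the hydrophobicity index *H*, the
  side-chain pKₐ *K*, and the molecular mass *M* of each amino acid.
  Hydrophobic residues are depleted at nucleic-acid interfaces, positively
  charged (high-pKₐ) residues enriched (the phosphate backbone is negatively
  charged), and residue size constrains interface packing. The package ships
  a default table (Kyte–Doolittle *H*; side-chain pKₐ for D, E, C, H, Y, K,
  R with a 0 sentinel elsewhere; monoisotopic residue masses in Da) as a
  plain TSV config, so an alternative scale can be swapped in without code
  changes. Each feature is min–max scaled to [0, 1] over the 20 standard
  amino acids — an RBF kernel needs commensurate feature scales, and mass in
  daltons would otherwise dwarf everything else. Ambiguity codes (X, B, Z,
  J, U, O) map to per-feature means.

* **Conservation descriptors (`descriptors`)** — for each query position,
  the residues aligned to it across the query's homologues are collected
  (query included, gaps and ambiguity codes excluded), and the mean and
  population standard deviation of each of *H*, *K*, *M* over that column
  are computed: six numbers per position, written H̄±σ, K̄±σ, M̄±σ.
  Binding residues tend to be conserved, so a high K̄ with small σ marks a
  position whose positive charge is evolutionarily maintained — exactly the
  kind of biochemical conservation a general-purpose PSSM does not expose
  directly. Means are scaled with the same per-feature bounds as the
  single-residue features; σ is scaled by the feature's raw range.

* **PSSM (`pssm`)** — the 20 per-position log-odds scores of a
  position-specific scoring matrix, as produced by an iterative
  profile search (three iterations, E-value threshold 1e-5 in the bundled
  `runPsiBlast()` wrapper). Raw scores are mapped through the logistic
  function 1/(1+e^−x), a strictly increasing map sending 0 to 0.5, so
  ordering is preserved and values land in (0, 1).

A full-feature window therefore encodes 11 × (3 + 6 + 20) = 319 values.
Within each per-residue block the order is fixed — [H, K, M], the six
descriptors, the 20 PSSM columns — which the kernel is indifferent to but
reproducibility is not.

## Design choices worth knowing about

* **Population σ, query included.** The column statistics divide by the
  observation count (not count − 1), so a single-observation column has
  σ = 0 rather than being undefined; including the query guarantees every
  column is non-empty. Homologues are unweighted; with tabular pairwise
  input, duplicate subjects are collapsed and only the best-scoring local
  alignment of a subject contributes at each query position.
* **Inclusive 3.5 Å cutoff; hydrogens excluded.** The contact rule compares
  with ≤, hydrogens and waters are excluded from distance computation
  (crystal structures typically lack hydrogens), only the first model of
  multi-model files is used, and each protein chain is labelled against the
  union of all nucleic chains of the requested kind. Non-standard amino
  acids map to 'X' and keep their labels.
* **Training vs prediction windows.** The n − w + 1 scheme leaves the five
  terminal residues on each side without instances; a report, however,
  must cover every residue. Training mode replicates the windowing scheme
  exactly; prediction mode emits one window per residue with all-zero
  padding blocks at the termini (zero is the post-scaling floor, neutral
  relative to the [0, 1] features under the RBF distance).
* **The solver.** The max-margin fit uses libsvm (through e1071) behind a
  thin contract — fit plus real-valued decision outputs — with solver
  tolerance 1e-3; the original method used an equally off-the-shelf SVM
  package, and re-deriving SMO would add nothing. Scores are oriented so
  that higher always means more binding-like. Class weights default to 1:
  operating points come from threshold sweeps, not from reweighting.
* **Ties, thresholds, confidence.** A residue is called '+' iff its output
  `o` is at least the threshold `t`. Operating points are step lookups on
  the cross-validated ROC staircase, taken on the conservative side: the
  smallest threshold whose specificity reaches the requested level, or the
  largest threshold whose sensitivity does. Confidence is an empirical
  rank: for a positive call, the fraction of calibration positives scoring
  strictly below `o` (= 1 − sensitivity at `o`); for a negative call, the
  fraction of calibration negatives scoring at or above `o` (= 1 −
  specificity at `o`). The overview digit is ⌊10 × confidence⌋ clamped
  to 9.
* **Grid search tie-break.** Cross-validated grid search over γ and C
  breaks ties toward smaller C, then smaller γ — the smoother, more
  regularized boundary. Default grids are γ ∈ {0.01, 0.05, 0.1, 0.5, 1},
  C ∈ {0.5, 1, 2, 5, 10}.

## What the synthetic generators emulate

Real training data require protein–nucleic acid complexes and large-scale
homology searches; the package's generators reproduce the statistical shape
of those inputs deterministically (every output is a pure function of spec
and seed):

* `synthComplex()` writes a toy PDB complex — a straight-line protein
  backbone with 3.8 Å CA spacing and a nucleic chain whose phosphates sit
  at exact, controllable distances from chosen residues. Chemically naive,
  but the planted distances make the contact rule testable against ground
  truth, including the inclusive boundary at exactly 3.5 Å.
* `synthAlignment()` mutates homologue copies of a query independently per
  position at given rates, with optional gaps; lower rates plant column
  conservation.
* `synthDataset()` emulates the study conditions as a whole: 60 sequences
  of 120 residues; 15% binding residues laid out in contiguous patches
  (interfaces are locally clustered); binding positions enriched for basic
  and polar residues (R, K, H, N, Q, S, T, Y) and non-binding positions for
  hydrophobic and acidic ones; 30 homologues per sequence with mutation
  rate 0.10 at binding positions versus 0.40 elsewhere and a 5% gap rate;
  synthetic PSSMs computed from the alignments themselves as column
  log-odds against a uniform background with pseudocount 1, so the PSSM
  path needs no external search tool. The `signal` parameter scales every
  label–feature coupling at once — including the gap-rate contrast, which
  would otherwise leak labels through column observation counts — so
  `signal = 0` is a genuine null model whose cross-validated AUC sits at
  chance.

What passing on these fixtures does **not** show: real interfaces are not
straight-line geometries, real homologue sets are not i.i.d. uniform
mutations of the query, and real binding-site composition signals are far
weaker and more entangled than the planted ones. The generators validate
the machinery (encoding, solver, calibration, bookkeeping), not the
biological accuracy attainable on curated structure-derived datasets,
which additionally depends on the homology database and redundancy
filtering used.

## Problem sizes and evaluation settings

The packaged evaluation runs fivefold cross-validation at γ = 0.1, C = 1
on the default synthetic conditions (60 × 120 residues, 6600 training
instances), chosen as the smallest scale at which the planted-signal
ordering — biochemical features alone, plus conservation descriptors, plus
PSSM — is stable across seeds. Folds are stratified at the instance level
to preserve the ~15% positive rate per fold; a `groupBySequence` option
assigns whole sequences to folds instead, since overlapping windows of one
sequence can otherwise straddle folds and flatter the estimate slightly.

On these conditions the expected picture is: biochemical features alone
reach a cross-validated AUC around 0.8; adding the conservation
descriptors lifts the AUC markedly (the planted conservation contrast is
informative); the full encoding exceeds 0.99; and the null generator stays
within [0.45, 0.55]. The qualitative ordering — evolutionary information
helps, and the descriptors add signal beyond the biochemical features —
mirrors what is observed on structure-derived datasets, where absolute
numbers are lower throughout.

## Degenerate inputs and numerical conventions

Zero-denominator metrics return 0 with a degeneracy flag instead of
failing mid-sweep. Empty atom sets, single-class training input, missing
nucleic partners, mismatched encoding descriptors and malformed PSSM rows
are all hard errors, never silent defaults. ROC curves carry ±∞ sentinel
thresholds so the staircase always spans (1, 1) to (0, 0); tied scores are
grouped into single points, making the trapezoidal AUC equal to the
tie-corrected Mann–Whitney statistic. A requested level met only at a
sentinel threshold is flagged as saturated.

## Known limitations

The H/K/M scale values are a documented choice, not canonical constants;
results shift slightly under alternative hydrophobicity scales (the TSV
config exists for exactly that experiment). PSSM and descriptor rescaling
before SVM input is likewise a package convention. Instance-level folding
lets windows of one sequence share folds (use `groupBySequence` for the
stricter protocol). The PDB reader handles the common single-model,
standard-residue case; mmCIF is out of scope.
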