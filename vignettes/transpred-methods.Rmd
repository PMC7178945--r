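---
title: "Methods: stacked composition and homology classification of transporters"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: stacked composition and homology classification of transporters}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(transpred)
```

## The problem and the model

Distinguishing membrane transporters from other proteins using sequence
alone is hard for either of the two classical approaches on its own.
Homology transfer against a curated transporter database is precise when a
close hit exists but blind otherwise; sequence-composition machine learning
generalizes but ignores evolutionary context. `transpred` stacks the two:
six base classifiers vote, and a trained meta-classifier — rather than a
fixed rule such as majority voting — learns when to trust which vote. The
value of stacking comes from the low correlation between the two families
of base classifiers: they err on different queries.

### psi-composition descriptors

All descriptors are defined over the 20 natural amino acids. Sanitation
therefore *deletes* ambiguity codes (B, J, O, U, X, Z), gaps and stop marks
rather than remapping them, and the length L that normalizes every
composition is the post-filter length.

For a query `Q`, homologs are retrieved by PSI-BLAST (3 iterations,
e-value cutoff 0.001; a single-pass BLAST variant gives the
"blast-composition"). Only the gap-free aligned region of each hit is kept
— unaligned subject stretches carry no evidence of shared ancestry. The
psi-composition is the arithmetic mean of the per-sequence descriptor over
the query and its n regions, i.e. `(1/(n+1)) Σ X(P)`. With n = 0 it
degrades gracefully to the plain descriptor, which is also the fallback
when no search backend is available.

Three descriptor kinds are averaged this way:

* **AAC** (length 20) and **PAAC** (length 400, overlapping dipeptides,
  row-major alphabetical order) are pure counting descriptors.
* **PseAAC** (length 20 + λ) augments the residue frequencies with
  sequence-order correlation factors θ_j: the mean squared difference of
  standardized hydrophobicity, hydrophilicity and side-chain mass between
  residues j apart, j = 1…λ. The whole vector is normalized by
  `1 + ω Σθ`, so it sums to 1.

Component order is fixed (alphabetical residues; row-major pairs; θ tail
last) so serialized feature tables and model schemas are portable.

### Parameters that matter

| parameter | default | meaning and rationale |
|---|---|---|
| λ (PseAAC depth) | 30 | positional lag of the correlation factors; must satisfy λ < L. The source method never states its value; 30 is a conventional choice for proteins of a few hundred residues and is configurable. |
| ω (PseAAC weight) | 0.05 | weight of the θ tail; 0.05 is the canonical default. The conventional user range is [0.05, 0.7]; the implementation accepts ω ≥ 0 (with a warning outside the range) so the ω → 0 limit — PseAAC collapsing onto AAC — is testable. |
| e-value cutoff | 0.001 | hit retention for psi-composition retrieval. |
| iterations | 3 | PSI-BLAST rounds; hits are taken from the final round only. |
| SVM grid | C ∈ 2^{−5..15}, γ ∈ 2^{−15..3} (log₂ step 2) | customary RBF lattice; selection by stratified 5-fold CV accuracy, ties to smaller C then smaller γ. Training data are balanced, so accuracy is an adequate selection metric. |
| meta folds k | 10 | granularity of meta-feature cross-validation. |
| GBM grid | trees ∈ {50,100,150}, depth ∈ {1,2,3}, shrinkage 0.1 | selected by inner 5-fold CV accuracy; common defaults of gradient boosting on tiny feature spaces. |

Properties ship as a versioned in-code asset (Tanford hydrophobicity,
Hopp–Woods hydrophilicity, textbook side-chain masses). Tests assert the
standardization invariants (mean 0, population variance 1 over the 20
residues) rather than specific raw numbers, so substituting an equivalent
table rescales nothing downstream.

### Homology-transfer rules

A hit table in the 12 standard BLAST tabular columns is filtered by one of
three profiles (exact; strict similarity with coverage and length
conditions; permissive e-value-only). Decisions that the tabular format
forces and the implementation fixes:

* "reported e-value 0" is taken literally — the tool printed 0.0, i.e.
  below representable range — combined with 100% identity; that is what an
  exact match operationally yields.
* Coverage is computed from inclusive alignment coordinate spans
  (`(qend−qstart+1)/qlen`), not gap-adjusted alignment lengths, because
  only the former is reproducible from the 12 standard columns.
* Length difference is normalized by the longer of the two sequences,
  making the condition symmetric and bounded by 1.
* A stray percent sign in the published permissive threshold ("1e−8%") is
  treated as a typographical artifact; the cutoff is 1e−8.

These rules are monotone: relaxing any threshold can only turn NT into T,
and an exact-profile T implies a permissive-profile T. Both properties are
tested on seeded random hit tables against a brute-force filter.

### Stacking

Meta-features are **hard labels** {0, 1}, not scores: the homology rules
only produce labels, and mixing calibrated probabilities with binary votes
would give the SVMs an arbitrary resolution advantage. Rows of the
meta-training set come from a stratified 10-fold pass (single pass, not
repeated): the vote of a trainable base for instance *i* is produced by a
model fitted on the folds that exclude *i*; rule bases are deterministic
and fold-independent. `k = n` is honoured as leave-one-out. A memorizing
test learner asserts the no-leakage property directly.

SVM hyperparameters are selected **once per feature kind** on the full
training set; the per-fold refits reuse them. The alternative — re-tuning
inside every meta fold — multiplies cost roughly tenfold and changes
nothing about vote leakage (the refit never sees the held-out fold); the
residual optimism affects only which (C, γ) the refits share. This is the
package's reading of an underspecified step.

All randomness (fold plans, learner seeds) derives from one master seed
recorded in the model bundle; training twice with the same seed yields
byte-identical serialized models.

### In-package learners

The environment provides no SVM or gradient-boosting library, so both
learners are implemented here and are deliberately boring:

* **RBF C-SVC** trained by SMO with maximal-violating-pair working-set
  selection on a precomputed kernel matrix (stopping tolerance 1e−3, the
  libsvm convention; deterministic, no shrinking heuristics). Grid search
  precomputes one squared-distance matrix per fold, so scanning γ costs one
  `exp()` per kernel entry and scanning C only re-runs the solver.
  Decision values were cross-checked against an independent SMO
  implementation during development and agree to the stopping tolerance.
* **GBM** with Bernoulli deviance, shallow regression trees on the six
  binary votes, Newton leaf estimates, shrinkage 0.1, no subsampling —
  deterministic by construction. Tree-count selection uses staged
  prediction, so the scan over {50, 100, 150} trees is nearly free.

Compositions already live on a common [0, 1] scale, so no feature scaling
is applied before the RBF kernel.

## Numerical choices and degenerate inputs

* MCC is defined as 0 when its denominator vanishes (the "no better than
  random" convention); rates with empty denominators are NaN rather than
  silently 0.
* Repeated-CV metrics are computed from confusion counts pooled across the
  k folds of each repeat, then averaged over repeats. Pooling is invariant
  to fold order and stable when folds are small; averaging tiny per-fold
  rates is not.
* SVM label ties (decision value exactly 0) resolve to T; grid-search ties
  prefer smaller C then smaller γ; GBM selection ties prefer fewer, then
  shallower trees.
* Sequences shorter than λ + 1 are an error for PseAAC by default; an
  explicit clamp mode sets λ = L − 1 with a warning. Homolog regions
  shorter than the descriptor minimum (λ + 1 for PseAAC, 2 for PAAC) are
  skipped with a warning and do not count toward n.
* Duplicate FASTA ids are an error, never silently suffixed: ids key
  feature rows, meta rows and prediction reports.

## What the synthetic world does and does not establish

The generators emulate exactly the artifacts the pipeline consumes: *(i)*
two-class sequence sets whose classes differ in residue composition
(transporters hydrophobic-enriched, non-transporters charged/polar-
enriched — a caricature of membrane-spanning versus soluble proteins);
*(ii)* homolog sets produced by uniform point substitution at a target
identity; *(iii)* hit tables that are label-coupled in profile-aware mode
(every T query gets one all-profiles-passing hit, every NT query only
failing hits).

Defaults state the test world: 200 sequences per class, lengths uniform on
200–600 (typical transporter lengths), 5 homologs per query at 90%
identity. Under this world the end-to-end pipeline must reach ≥ 0.90
held-out accuracy and be bit-reproducible under one master seed.

A green synthetic run establishes that descriptors, retrieval plumbing,
fold bookkeeping, the learners and the ensemble wiring are correct and
deterministic. It does **not** establish biological performance: real
transporter discrimination has overlapping composition distributions,
homologs with indels and domain-level conservation, and a reference
database that is not label-perfect — none of which the generators model
(the profile-aware hit tables make the homology rules exactly right by
construction, which no real database is).

## Known limitations

* The external PSI-BLAST backend parses tabular output with comment lines
  and keeps the final iteration; it is exercised against fixture stubs,
  not a live database, in the test suite.
* Only one HSP (best bitscore) per subject contributes a region;
  concatenating multiple HSPs is not supported.
* Meta-features are binary; class-probability stacking is out of scope.
* The SMO solver stores the full kernel matrix; training is comfortable at
  thousands of sequences but not at hundreds of thousands.
* Amphiphilic (type-2) PseAAC and gapped dipeptides are not implemented.
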