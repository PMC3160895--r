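---
title: "Predicting peptide reactivity to pooled human antibodies and designing de novo epitope peptides"
author: "epireact"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Predicting peptide reactivity to pooled human antibodies and designing de novo epitope peptides}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(epireact)
```

## The problem

Short peptides arrayed on a solid support and incubated with pooled human
antibodies (IVIg) either bind with high signal ("positive", reactivity
10000–65536 in the assay's units) or essentially not at all ("negative",
reactivity 1–1000). Whether the reactivity of a peptide can be predicted
from its sequence alone is an open question in linear B-cell epitope
biology. `epireact` implements a complete knowledge-based pipeline for this
question: featurization, a logistic-regression classifier with feature
selection, leakage-aware leave-one-out evaluation, and a generator of novel
peptides with prescribed predicted reactivity.

## The feature model

Each peptide is described by 37 features in two blocks.

**Sequence-derived (31).** Sequence length; the isoelectric point (the pH
at which the Henderson–Hasselbalch net charge over the termini and the
D/E/C/Y/H/K/R side chains vanishes, solved by bisection on \[0, 14\] to a
pH tolerance of 1e-4 with an EMBOSS-style pKa table); the occurrence count
of each of the 24 alphabet symbols (20 residues plus the ambiguity codes
B, X, Z, J, each counted as itself); and five propensity-scale features —
antigenicity (Kolaskar), accessibility (Janin), hydrophilicity (Parker),
flexibility (Bhaskaran) and Chou–Fasman beta-turn propensity. A scale
feature is the maximum over all sliding windows of 9 residues of the
within-window statistic of the per-residue scale values. The window length
reflects the typical 8–10 residue antibody binding footprint.

Two windowing choices are deliberately explicit because the within-window
statistic is genuinely open: the default aggregates by the *mean* (the
standard smoothing for propensity profiles; for homopolymers the mean and
the max coincide, so the worked examples are unaffected), and a peptide
shorter than the window is summarized by one window covering the whole
sequence. Ambiguity codes contribute derived scale values: B = (N+D)/2,
Z = (Q+E)/2, J = (L+I)/2 and X the grand mean of the 20 residues.

**Dataset-derived (6).** Every peptide is aligned against every labelled
reference peptide with both Needleman–Wunsch (global) and Smith–Waterman
(local) affine-gap alignment (BLOSUM50; a gap of length L costs
`10 + L × 1`; the matrix's own B/Z/X rows score the ambiguity codes and J
falls back to the X row, which BLOSUM50 does not define). The features are
the maximum score against the negative references (`MaxScore0`), against
the positive references (`MaxScore1`) and their difference
(`DiffMaxScore`), per alignment mode — the classification-by-homology
idea: similar sequences have similar reactivities. The query itself is
always excluded from the maxima.

All 37 columns are min–max normalized to \[0, 1\] on the training table;
test peptides are normalized with the *training* minima and maxima and
clipped. Raw (unnormalized) alignment scores enter the table; no
length-correction is applied before the table-level normalization.

## Classifier, feature selection and leakage-aware evaluation

The classifier is maximum-likelihood logistic regression. Three selection
routes mirror the three classical subsets:

* **A (none)** — all 37 features;
* **B (M5)** — collinear features are first eliminated greedily (of any
  pair with |r| > 0.95, the member with the smaller absolute univariate
  slope is dropped), then backward elimination removes the feature with the
  smallest standardized coefficient while the Akaike criterion does not
  worsen, ties broken lexicographically;
* **C (LASSO)** — an L1-penalized logistic fit with the penalty chosen by
  5-fold cross-validated deviance (folds assigned deterministically by row
  order), keeping features with non-zero coefficients.

Coefficients of removed features are stored as exact zeros, so a trained
model always carries a full-length coefficient vector. On perfect
separation the fit falls back to a small L2 ridge (1e-6) with a warning.

Because `MaxScore` features embed the class labels of the reference set,
naive cross-validation would leak the held-out label into its own features.
`loocv()` therefore masks the held-out index from every reference maximum,
re-derives the normalization (and, optionally, the selection) on the n−1
retained peptides, refits, and only then scores the held-out peptide
against the retained references. The chance-level behaviour of this
discipline is itself tested: on label-randomized data the held-out AUROC
must sit at 0.5. A small caveat worth knowing: leave-one-out with many
features is slightly *pessimistic* at small n (each fold's model is fitted
on a set depleted of the held-out class), so the null check uses 200
peptides, where that bias is well inside the ±0.05 tolerance of the test.

Metrics are computed at threshold 0.5 (accuracy, sensitivity, specificity,
precision, F-measure = 2·Sens·Prec/(Sens+Prec)), plus the Brier score,
rank-based AUROC (ties counted half) and step-interpolated AUPR.
Univariate single regression coefficients (SRCs — the slope of the 0/1
class on each standardized feature) serve as the sign/importance check for
fitted coefficients.

## The de novo generator

`generate_candidates()` produces lists of novel 15-mers predicted to be
highly reactive (H), non-reactive (L) or intermediate (M), under two
novelty rules: (1) no common substring of more than 3 residues with any
training or test sequence, and (2) at most 5 positional identities within
any window of 11 in every ungapped sliding comparison against the training
set (gapped comparison is deliberately not used for rule 2; the rule is
stated over positions).

1. **Clustering.** Local-alignment scores are normalized by the geometric
   mean of the self-scores, `d = 1 − s_ij/√(s_ii·s_jj)` — a symmetric
   choice that maps non-negative local scores into \[0, 1\] — and
   complete-linkage clustering is cut at 0.7, which bounds every cluster's
   diameter by 0.7.
2. **Cluster typing.** H clusters: ≥ 5 members, all positive; L: ≥ 8, all
   negative; M: ≥ 5 with a positive fraction within ±5 points of the
   training positive fraction.
3. **Cluster alignment.** A star-progressive multiple alignment around the
   medoid (largest summed local score), merged under "once a gap, always a
   gap" — chosen for determinism at desk scale. Column conservation is the
   sequence-logo information `log2(20) − H` in bits, entropy taken over
   non-gap symbols with no small-sample correction; all-gap columns carry
   0 bits.
4. **Motif extraction.** For each 15-mer member, positions are visited in
   decreasing column information (ties by ascending position) and fixed
   unless fixing would create a run of 4 consecutive fixed residues whose
   word occurs in the reference 4-mer index. One further pass is required
   to make the two novelty rules jointly satisfiable: since the source
   sequence is itself a training member, every fixed position is an
   identity against it, so the extractor releases the least-conserved
   fixed positions (ties by descending position) until no 11-window holds
   more than 5 fixed residues. Without this cap a 15-mer motif retains
   ~12 fixed positions and *every* enumerated candidate violates rule 2 —
   the constraint-1-only reading is internally inconsistent. Variable
   positions may take residues from their BLOSUM50 group (a fixed
   eight-group partition obtained by complete-linkage clustering of the
   20 residues under the same geometric-normalized BLOSUM50 distance:
   AG, C, DENQ, FWY, HKR, ILMV, P, ST) together with the residues observed
   in their alignment column, pruned of choices that recreate an indexed
   4-mer with the flanking fixed runs; if the group offers nothing
   admissible the whole alphabet is searched, and a position empty even
   then marks the motif non-viable.
5. **Enumeration, filtering, ranking.** Motifs are expanded (Cartesian
   product, down-sampled to a per-motif cap when larger), deduplicated,
   capped per class, re-checked by the novelty filter — the filter, not
   the motif construction, is the final gate — and scored by the trained
   model, with features computed against the training references and
   normalized on the training table. H takes the top-scoring candidates,
   L the bottom, M a uniform random sample, ties broken by lexicographic
   sequence order. All sampling flows from the single `run_config()` seed.

## The synthetic generator

`simulate_peptides()` emulates the statistical structure the pipeline
assumes: ~25% positives; lengths mostly 15 (85%), some 13 (10%) and rare
9/16/18/20/21; each positive carries one mutated copy (default 10%
per-position mutation) of one of a few family motifs of length 8 — the
low end of the binding-footprint range, so that even 9-mers can host it —
implanted at a random offset; negatives are background with a fraction
(default 10%) carrying decoy motifs so length or composition alone cannot
solve the task; ambiguity codes are injected at 0.1% to exercise those
code paths; reactivities are uniform on the class ranges. Background
residue usage is uniform over the 20 standard residues.

What the generator does *not* model: real amino-acid background
frequencies, assay noise near the class boundaries, shared-protein
provenance of peptides, or any actual epitope biology. Passing tests on
synthetic data therefore demonstrate the pipeline's statistical soundness
(signal recovery, leak-freedom, constraint conservation), not biological
accuracy on real assay data.

The de novo property runs use a decoy-rich variant (decoy fraction 0.6,
160 peptides) so that all-negative clusters of size ≥ 8 reliably exist —
in the real assay data negative peptides form sequence families too,
which is exactly what makes L clusters selectable there.

## Problem sizes and numerical choices

The shipped tests run at desk scale: leave-one-out at n = 200–300,
alignment-oracle equivalence on sequences of length ≤ 6 (where exhaustive
path enumeration is feasible), de novo runs on 120–160 training peptides
with 20 candidates per class. Other defaults: bisection interval 1e-4 for
the isoelectric point; collinearity threshold 0.95; enumeration cap 1e5
per motif and pool cap 2e4 per class (both seeded down-samples);
classification threshold 0.5. Degenerate cases are defined, not special-
cased: constant features normalize to 0 and get SRC 0 with a warning,
all-gap columns carry 0 bits, empty local alignments score 0.

## Known limitations

* The published assay training/test sets are not redistributable, so the
  headline cross-validation and challenge-score numbers of the original
  study are not reproducible here; the package's claims are the
  property-level ones above.
* The M-cluster rule needs mixed clusters whose composition matches the
  training fraction; on small synthetic sets such clusters are rare, so
  the examples emit H and L lists only.
* The star-progressive MSA is a deterministic desk-scale heuristic, not an
  optimal multiple alignment; wide clusters accumulate gap columns.
* Exact DP alignment is quadratic in the set size; tens of thousands of
  peptides (the original assay scale) call for hours of CPU, not the
  minutes of the examples.

## A worked example

```{r example, eval = FALSE}
library(epireact)

train <- simulate_peptides(sim_config(n_peptides = 160, seed = 1))
cv <- loocv(train, run_config(seed = 1))
cv$report

fit <- train_model(train, run_config(seed = 1), selection = "m5")
print(fit$model)
```
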