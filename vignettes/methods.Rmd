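---
title: "Methods: models, parameters and design choices in petminer"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: models, parameters and design choices in petminer}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(petminer)
```

## What this package models

`petminer` is a desk-scale toolkit for the computational side of mining
thermotolerant enzyme candidates — the motivating case being PET
hydrolases, serine hydrolases that cleave the ester bonds of
poly(ethylene terephthalate) — from protein sequence collections. It
covers four statistical components and the pipeline that connects them:

1. a **profile hidden Markov model** (HMM) of a sequence family, built
   from a multiple sequence alignment and used to score and rank
   candidate sequences in log-odds bits;
2. a **thermophilicity classifier** over compositional sequence features,
   used when a hit's source organism has no measured optimal growth
   temperature (OGT);
3. **activity-discrimination analyses** that ask whether family HMM
   scores can separate catalytically active members from inactive
   homologs (score method and difference method), evaluated by
   cross-validated ROC AUC and Spearman correlation;
4. **positional chi-squared tests** that ask whether any alignment column
   is associated with activity.

Every component can be exercised end-to-end on synthetic data with known
ground truth; the generators are part of the package's tested surface,
not throwaway fixtures.

## The profile HMM

### Architecture

The model is Plan7-like with `M` match states taken from the alignment
columns whose gap fraction is at most 0.5. Each match state emits one of
the 20 residues; insert states (one between consecutive match states)
emit background residues; delete states are silent. Scoring is local and
single-hit:

* flanking states `N` and `C` emit background residues with a geometric
  self-loop of parameter `q`;
* entry from the begin state is uniform over match states (probability
  `1/M` each);
* exit to the end state is allowed from every match state `k` with
  probability `1/(M - k + 1)`, which makes the exit point uniform, and
  from the final delete state.

The null model emits i.i.d. background residues with geometric length of
parameter `r = M/(M + 1)`, matched to the model length; the flank
self-loop uses the same `q = r`. The reported **bit score** is
`log2 P(seq | model) / P(seq | null)`. Because emissions in the flanks
and inserts default to the background, they cancel in the odds and the
score is carried by the match columns, as it should be.

These choices mirror the defaults of standard profile-HMM software in
spirit, but the resulting bit scores are *not* calibrated against any
external implementation, and no E-values are computed (that would
require a Gumbel-tail calibration we deliberately leave out). All
score thresholds downstream are therefore configuration, not constants.

### Estimation

Match emissions are weighted residue counts mixed with the background at
pseudocount weight 1 per state (Laplace-style); transitions are counted
from each row's state path with a +1 pseudocount per allowed transition
type. Sequence weighting is uniform by default with Henikoff
position-based weighting available. Two corners are handled
pragmatically: rows whose path would need an insert adjacent to a delete
(an I–D adjacency the architecture lacks) contribute their insert run as
if re-entering through a match, and ambiguity codes (B, Z, X, U, O) are
emitted with background probability in every state so they cancel in the
odds ratio.

### Numerical checking

The Forward and Viterbi recursions (implemented in C++ in log2 space)
are verified against an independent brute-force enumeration of *all*
state paths for toy models with up to 4 match states and sequences up to
length 5; agreement is at relative tolerance 1e-9 (observed ~1e-13).
The enumeration oracle lives in the test helpers and shares no code with
the DP kernels.

## Thermophilicity features and classifiers

A sequence is represented by 50 features: 20 amino-acid compositions,
10 selected g-gap dipeptide compositions, and 20 residue-type /
physicochemical features. A g-gap dipeptide `a(x)_g b` (residue `a`,
`g` arbitrary residues, then `b`) has composition = occurrence count /
`(L - g - 1)` windows; with g in {0, 1, 2} there are 1200 candidate
descriptors, from which the top 10 are selected by mean impurity
decrease (Gini importance) in a random forest fitted to the candidates
alone.

Feature-table choices the source material leaves open, and how we fixed
them:

* **Residue classes.** EFMR = {E,F,M,R}, tiny = {A,G,P,S}, small =
  {T,D}, IVYWREL = {I,V,Y,W,R,E,L}, positive = {R,K}, negative = {D,E}
  are fixed by convention. The remaining sets (acidic {D,E}; basic
  {K,R,H}; polar/non-polar; cyclic {F,W,Y,H,P}/acyclic; aliphatic
  {A,G,V,L,I}) follow standard textbook definitions and are plain R
  data a user can override. The *five-class* partition used by the
  positional tests (aliphatic including M, C, P; aromatic including H;
  positive; negative; polar {N,Q,S,T}) is a separate table, taken
  verbatim from the positional-testing convention, and is verified to
  partition the 20 residues exactly.
* **Ratios** (basic/acidic, non-polar/polar, acyclic/cyclic,
  charged/non-charged, (E+K)/(Q+H), charged/polar) are smoothed as
  `(count + 1)/(count + 1)` so they stay finite on short or extreme
  sequences. "Charged vs polar composition" is implemented as a
  smoothed ratio; the phrase is ambiguous in the literature and this
  reading keeps it commensurate with the other ratio features.
* **Constants.** Maximum solvent-accessible areas use a published
  theoretical-maximum scale; per-residue heat capacities and average
  masses use standard tables; the pKa set (termini plus D, E, C, Y, H,
  K, R) is a widely used 9-group set. Classifier behavior is invariant
  to rescaling any of these after standardization.
* **Ambiguity codes** are excluded from all composition denominators;
  molecular weight substitutes the mean residue mass and flags the
  result.

The isoelectric point is the root of the Henderson–Hasselbalch net
charge, found by bisection on [0, 14] to 1e-4 pH units; the charge is
strictly decreasing in pH so the root is unique. Bisection is checked
against a 0.001-pH-grid sign-change oracle.

Five methods are supported (SVM with RBF kernel, random forest,
logistic regression, Gaussian naive Bayes, k-nearest neighbor) across
four binary schemes (PM, MT, TH, MTH) over the thermal bands
psychrophilic < 15 °C, mesophilic 25–37 °C, thermophilic 45–70 °C,
hyperthermophilic > 80 °C; OGT values between bands are left unlabeled
rather than snapped to the nearest band. Distance/margin methods are
z-scored with training statistics; trees are not. Hyperparameter grids
are small and documented in `classifier_spec()`; the first grid point is
the method's conventional default (e.g. k = 5 for kNN, following the
common library default) and is what cross-validation uses, with the full
grid searched only in `train_classifier()` against a separate tuning
set. To avoid leakage between similar sequences, data can be clustered
at 40% identity (greedy representative clustering with exact
global-alignment identity — at desk scale no word-filter heuristic is
needed; identity = maximum matched residues / shorter length) and whole
clusters assigned to one partition or fold.

## Discrimination and positional statistics

The score method builds, within each of five stratified CV folds, an
HMM from the training actives' rows of one fixed master alignment
(all-gap columns dropped; no realignment per fold) and scores held-out
actives and inactives; the difference method additionally builds an
inactive-homolog HMM and uses the score difference. Held-out scores are
pooled; AUC uses the Mann–Whitney rank statistic with half-credit for
ties, and rho is the Spearman correlation with continuous activity
values where available.

Positional tests first remove columns with gaps in *more than* 90% of
rows (strictly; a column at exactly 90% is kept), then apply Pearson's
chi-squared test of independence (two-sided, no continuity correction)
at each remaining column, either over observed residues or over the
five residue classes. Gaps form their own category by default — an
insertion's presence is positional information — with a drop-gaps mode
available. Raw p-values below alpha (default 0.01) are flagged, mirroring
the positional screen convention; a Bonferroni column is reported but
never silently applied.

**Small-count behavior.** With a 5-or-more-category table and few
sequences, the chi-squared reference distribution is only approximate:
our null simulations show the raw scan is mildly *conservative* (true
size ≈ 0.008–0.009 at alpha = 0.01 with 80–240 rows) and reaches its
nominal size once expected counts are all ≳ 15 (≈ 320 rows for the
five-class grouping under typical compositions). The calibration test in
the acceptance suite therefore runs at 320 rows, where the asymptotic
claim is the right one to make; at realistic panel sizes (tens of
sequences) users should read the scan as slightly conservative, and the
`guard` mode warns whenever an expected count falls below 5. At
amino-acid resolution with small panels the conservatism is much
stronger (true size ~0.003 at 80 rows), which is worth remembering when
interpreting a negative scan.

## The triage pipeline

`run_pipeline()` chains: HMM search over the database → OGT mapping
(measured OGT where the table covers a hit; otherwise the MTH
thermophilicity classifier, with provenance recorded) → filters
(thermotolerant, i.e. OGT ≥ 50 °C or predicted thermophilic, AND bit
score strictly inside the source's window) → redundancy removal on the
mature sequence (residues after the annotated signal-peptide end), where
each identical-mature group keeps its highest-scoring member, ties
broken by id. The shipped default windows (> 100 bits for a broad
reference source, < 55 bits for a thermal-metagenome source) document
the intent of mining both high-confidence homologs and deliberately
diverse low-scorers, but since our bits are not externally calibrated
the windows are configuration. Every input sequence appears exactly once
in the report with all filter outcomes, and stage counts are logged.

## The synthetic generators

The generators emulate, at desk scale, the statistical structure the
real workflow faces; they do **not** emulate real protein biology
(no phylogenetic tree structure — star phylogeny only; no domain
architecture; i.i.d. background residues). Passing tests therefore
demonstrate correctness and calibration of the *methods*, not
performance on natural sequence corpora — reproducing corpus-dependent
headline numbers is explicitly out of scope.

* `gen_ogt_proteomes()` draws i.i.d. sequences from SwissProt-like
  background frequencies; the thermophile-like class shifts `delta`
  total probability mass proportionally onto IVYWREL ∪ {D, K},
  mimicking the charged/hydrophobic enrichment of thermophilic
  proteomes. OGTs are uniform in 55–70 °C (thermophilic band) vs
  25–37 °C (mesophilic). The package default `delta = 0.05` is a
  realistic moderate effect; calibration experiments use `delta = 0`
  (null) and `delta = 0.15` (strong, giving mean IVYWREL composition
  differences of ~0.12).
* `gen_homolog_family()` evolves descendants from a sampled ancestor by
  per-site substitution (default rate 0.05) and geometric indels
  (mean length 1.5, rate 0.01/site). Actives keep a catalytic motif —
  a G-x-S-x-G nucleophile elbow plus distal His and Asp, echoing the
  serine-hydrolase triad — immune to substitution and indels; inactives
  descend from their own sub-ancestor diverged at an extra 0.15/site
  (inactive homologs form a distinct subfamily, as they do in real
  families) and have every motif site ablated. The true alignment is
  tracked through every indel; insertions sharing a slot are
  left-aligned against each other, a bookkeeping convention rather than
  a homology claim.
* `plant_dipeptide_signal()` writes a known number of non-overlapping
  g-gap dipeptide occurrences into positive sequences, giving feature
  selection a recoverable ground truth.
* `gen_ogt_table()` covers an exact fraction of ids, exercising the
  classifier-fallback path.

All generators are deterministic functions of (config, seed); each
operation derives its own RNG stream from the master seed through a
fixed splitting rule, so adding one generator call never perturbs
another's output.

## Problem sizes and reproducibility

The shipped test and acceptance workloads use: 400 + 400 sequences of
120–180 residues for feature-selection recovery (10 seeds); 200 + 200
for classifier calibration; 20 + 20 family members of ancestor length
120 for discrimination (5 folds, 10 label permutations); 600-column
alignments with 320 rows and 20 permutations for chi-squared
calibration; and a 100-sequence database (20 family + 80 decoys) for
triage. These sizes were chosen so each statistical claim has adequate
power while the whole suite stays desk-scale. `scripts/acceptance.R`
re-runs all of them from scratch for any `--seed` and writes the
resulting quantities as JSON.

## Known limitations

* Bit scores are internally consistent but not comparable to any
  external HMM implementation; E-values are absent by design.
* The glocal and multi-hit alignment modes of full Plan7 are not
  implemented; DNA models are out of scope.
* The greedy identity clustering is exact but quadratic; it is meant
  for panels of hundreds, not databases of millions.
* The chi-squared scan at small panel sizes is conservative (see
  above), and, like the positional test it mirrors, it cannot see
  pairwise or higher-order covariation.
* Logistic regression on perfectly separable data relies on glm's
  converged-but-extreme fit; its tuning accuracy is still well-defined,
  and the other methods are preferable there.
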