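# petminer

`petminer` is an R toolkit for the computational stack behind mining
thermotolerant enzyme candidates — PET hydrolases being the motivating
family — from protein sequence collections. It is aimed at
computational biologists who want each stage of such a pipeline as an
inspectable, testable unit rather than a black box: profile-HMM homology
scoring, compositional thermophilicity classification, activity
discrimination, positional alignment statistics, and the candidate
triage that ties them together, plus synthetic-data generators with
known ground truth for validating all of it.

## The models at the core

**Profile HMM.** A Plan7-style model with `M` match states (alignment
columns with gap fraction ≤ 0.5), insert and silent delete states,
scored in local mode: uniform entry over match states, uniform exit
(`P(exit at k) = 1/(M−k+1)`), and background-emitting flanks. Scores are
log-odds bits against an i.i.d. background null with geometric length
matched to the model:

```
bits(x) = log2 [ P(x | HMM, local) / P(x | null) ]
```

computed by the Forward algorithm (Viterbi and its state path are also
available). The implementation is verified against exhaustive
enumeration of all state paths on small models.

**Thermophilicity classification.** Sequences are represented by 50
features — 20 amino-acid compositions, 10 g-gap dipeptide compositions
`a(x)_g b` selected from 1200 candidates (g ∈ {0,1,2}) by random-forest
Gini importance, and 20 residue-type/physicochemical features (class
compositions and ratios, mean max-ASA, (E+K)/(Q+H), IVYWREL
composition, molecular weight, heat capacity). Binary classifiers
(SVM, random forest, logistic regression, Gaussian naive Bayes, kNN)
are trained over the thermal bands psychrophilic <15 °C, mesophilic
25–37 °C, thermophilic 45–70 °C, hyperthermophilic >80 °C, in the
schemes PM, MT, TH and MTH, with cluster-aware splits at 40% identity.

**Discrimination and positional tests.** The score method asks whether
an active-family HMM's bits separate actives from inactive homologs
under fivefold CV (Mann–Whitney AUC, Spearman ρ vs activity); the
difference method scores with bits(active HMM) − bits(inactive HMM).
Per-column chi-squared tests of independence (residue- or
residue-class-resolution, gaps as their own category, columns with >90%
gaps removed) screen for activity-associated positions.

**Triage.** `hmm_search → map_ogt → apply_filters → dedup_candidates`:
hits are thermotolerant if their measured OGT is ≥ 50 °C, or, when no
OGT is known, if the classifier predicts the thermophilic side; score
windows are per-source and strict at both ends; redundancy is removed
on the mature sequence (after the annotated signal peptide), keeping
each group's top scorer.

## Worked example

Generate a homolog family whose actives carry an intact catalytic motif
(G-x-S-x-G elbow plus distal His/Asp) and whose inactives are a
diverged, motif-ablated subfamily; build an HMM from the true
alignment; and test whether HMM bits discriminate activity:

```r
library(petminer)

fam <- gen_homolog_family(n_active = 20, n_inactive = 20,
                          length = 120, seed = 42)
hmm <- build_phmm(fam$alignment)
hmm
#> profile_hmm: 120 match states (from 145 alignment columns)

res <- discriminate_score_method(fam$records, fam$alignment,
                                 folds = 5, seed = 1)
res
#> score-method discrimination: pooled AUC 1.000, Spearman rho 0.879

head(res$scores, 3)
#> # A tibble: 3 × 4
#>   id       fold activity_label score
#>   <chr>   <int> <chr>          <dbl>
#> 1 act_001     3 active          388.
#> 2 act_002     4 active          399.
#> 3 act_003     5 active          396.
```

Held-out actives score ~390–430 bits under the family model while
unrelated background sequences score near zero
(`hmm_search(hmm, decoys)` gives −2.5 to 0.4 bits here), so the pooled
AUC of 1.0 says the two groups are perfectly rank-separated in this
synthetic, strongly separable setting; ρ = 0.879 is the Spearman
correlation between held-out bits and the simulated continuous
activities. On hard real panels these numbers drop sharply — which is
exactly what the discrimination analyses are for.

The same components run from the shell via the thin CLI:

```sh
Rscript inst/cli/petminer.R hmmbuild --aln family.aln.fasta --out model.json
Rscript inst/cli/petminer.R hmmscore --model model.json --in db.fasta --out hits.tsv
Rscript inst/cli/petminer.R mine --db db.fasta --seed-aln family.aln.fasta \
    --ogt ogt.tsv --window 100,Inf --out report.tsv
```

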