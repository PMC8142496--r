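---
title: "Predicting phosphorylation sites with phosml: models, features and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Predicting phosphorylation sites with phosml}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The problem

Protein phosphorylation — the kinase-catalysed addition of a phosphate group
to a serine, threonine or tyrosine side chain — is the most abundant
post-translational modification in eukaryotes, and its dysregulation is
implicated in cancer and neurodegenerative disease. Experimental mapping of
phosphosites (mass spectrometry, mutagenesis) is slow and error-prone, so
sequence-based classifiers that score every candidate S/T/Y residue in a
protein are a standard complement.

`phosml` implements one such classifier family end to end. A candidate site
is represented by its **21-residue window** (the central S/T/Y plus ten
flanking residues on each side), encoded under up to five feature schemes,
filtered through a two-stage information-theoretic feature selection, and
classified by a random forest or an RBF-kernel SVM. Each central-residue
type (pS, pT, pY) gets its own dataset and model, since the local sequence
and structural context of the three acceptor residues differ.

## Windows and datasets

Sites are 1-based positions validated against the sequence. Windows near a
terminus are padded with `'X'` rather than discarded, so every annotated
site is usable; `drop_edge_sites = TRUE` gives the alternative behaviour.
Non-standard residues (U, B, Z, `*`, ...) are likewise masked to `'X'`,
keeping the encoder alphabet closed. The pad encodes to **all zeros in every
scheme** — neutral for both tree splits and RBF distances.

Positives are the annotated phosphosites. Under the default negative
policy, negatives are every other S/T/Y of the same residue type in
proteins that carry at least one positive annotation; restricting negatives
to positive-bearing proteins avoids polluting the negative class with
proteins that were simply never assayed. The labelled set is split
80/20 into training and held-out test partitions, stratified by label with
a seeded RNG (largest-remainder allocation keeps the stratum sizes summing
to `round(0.8 n)`), and model assessment uses stratified five-fold
cross-validation on the training partition plus a final evaluation on the
untouched test partition.

## Feature schemes

| scheme | per position | width (21-mer) | level |
|--------|--------------|----------------|-------|
| PP physicochemical | 7 normalised scales | 147 | residue |
| BE one-hot sequence | 20 indicator bits | 420 | residue |
| SS structural | ASA + C/H/E one-hot + disorder flag | 105 | residue |
| FF functional terms | one bit per GO/domain/KEGG term | vocabulary size | protein |
| FA annotations | one bit per UP_SEQ_FEATURE / UP_KEYWORDS term | vocabulary size | protein |

The seven bundled physicochemical scales (amino-acid composition,
flexibility, hydropathy, net charge, octanol–water partition, residue
volume, molecular weight) come from the published scales documented in the
header of `inst/extdata/aa_properties.tsv` and can be replaced by any table
of the same layout. Each scale is min–max normalised to [0, 1] over the 20
residues so that all features are commensurate — a prerequisite for the
RBF kernel, and harmless for trees.

One-hot columns are ordered alphabetically by one-letter code, so alanine
is `10000000000000000000` and serine `00000000000000010000`.

Structural profiles (secondary-structure state and a [0, 1] disorder score
per residue) are **inputs**, read from a TSV in the shape produced by
standard secondary-structure and disorder predictors; running those
predictors is out of scope. The disorder flag is 1 only for scores
*strictly above* 0.5: a residue scoring exactly 0.5 is ordered. ASA is a
per-amino-acid maximum-accessibility lookup, not a computed per-site value.

Functional and annotation features are **protein-level**: every fragment of
a protein carries the same term-membership bits, one column per term in the
vocabulary's persisted order. We deliberately do not replicate these bits
per window position — replication would add 21 identical copies of each
column, which carry no extra information and would distort the redundancy
term of mRMR. Proteins absent from every term encode as all-zero (with a
warning), since unannotated proteins are a fact of life.

## Two-stage feature selection

Both stages work on discretized columns: binary/indicator columns pass
through untouched, continuous columns are cut into three equal-frequency
bins (quantile breaks; if heavy ties collapse the quantiles, a midrange
split keeps the alphabet finite). Three bins keep the plug-in mutual
information estimator well conditioned at the sample sizes involved.

**Stage 1 — mRMR within each feature category.** Greedy
minimum-redundancy maximum-relevance ranking, difference (MID) form: the
first pick maximises `I(feature; label)`; each subsequent pick maximises
`I(f; label) − mean_s I(f; s)` over the already-selected features `s` of
that category. The quotient (MIQ) form is available via
`mrmr_rank(variant = "MIQ")`. The top 50 features of each category are
retained (fewer if the category is narrower). Running mRMR per category
keeps narrow categories (e.g. a small KEGG vocabulary) from being swamped
by the 420 one-hot columns.

**Stage 2 — symmetrical uncertainty on the pooled survivors.**
`SU(X, Y) = 2 I(X; Y) / (H(X) + H(Y))`, a normalised information gain in
[0, 1]. We read the information-gain numerator as the mutual information —
the standard convention in attribute-evaluation work; a conditional-entropy
reading would break the [0, 1] range. The survivors are ranked by SU
against the label and, by default, everything with `SU > 0` is kept: the
plug-in SU of a non-constant feature is essentially never exactly zero, so
the default cutoff only removes constant or exactly independent columns,
and the full ranking is persisted so any stricter cutoff (e.g. top-*n*)
can be applied afterwards without recomputation.

Everything is deterministic: ties in any ranking resolve to the lower
column index, with a `1e-12` tolerance so that mathematically tied criteria
computed along different floating-point paths still tie.

By default, selection (like SVM standardisation) is fitted on the
**training partition only**; `select_on = "all"` exists for strict
emulation of protocols that select before splitting, but is leakage-prone
and off by default.

## Classifiers

* **Random forest** (`randomForest`): 100 trees, `sqrt(p)` features per
  split, seeded. Scores are out-of-bag-style vote fractions on the
  `1/ntrees` grid.
* **SVM, RBF kernel** (`e1071`): `C = 1`, `gamma = 1/p`, columns
  standardised with training-set moments stored in the model. Platt-style
  probability calibration is enabled so the SVM yields graded scores —
  required for ROC/AUC.

These are the long-standing defaults of the underlying implementations; no
hyperparameter search is performed, and all values are exposed in the
configuration. Class imbalance is left as-is (a `class_weights` argument
exists but defaults off). Hard calls use a fixed 0.5 threshold, with a
score of exactly 0.5 called negative.

## Evaluation

From the confusion matrix: accuracy, sensitivity, specificity, precision,
F-score `2TP/(2TP+FP+FN)` and Matthews correlation coefficient. Zero
denominators: SN/SP/PRE/F are 0 when undefined (precision warns), and MCC
is 0 whenever a factor under the root vanishes — the usual conventions that
keep batch evaluation total. The ROC curve is sensitivity against
1 − specificity with thresholds at the distinct score values (ties
grouped, endpoints (0,0) and (1,1) always present); AUC is the trapezoidal
area, which on the tie-grouped curve equals the rank statistic
`P(s⁺ > s⁻) + ½ P(tie)` — both facts are property-tested against
brute-force pair counting.

## The synthetic study

Because real phosphoproteome data cannot ship with the package, the
`synth_config()` / `synth_bundle()` / `generate_bundle()` family generates
a complete, self-contained study: FASTA sequences, a labelled site table,
per-residue structural profiles, term vocabularies and the property table,
all reproducible bit-for-bit from one seed. Four signal knobs plant
class-conditional structure whose encoded column identities are recorded in
`truth$planted`, so selection can be scored against ground truth:

* flanking-composition bias (motif residues P/R/D at offsets ±1..3 of
  positive centres),
* disorder enrichment around positive centres (Beta(6, 2) versus a
  Beta(2, 6) background),
* coil bias near positive centres,
* protein-level annotation enrichment: proteins are "positive-rich" or
  "positive-poor", informative terms track that class while decoy terms do
  not — which is what makes protein-level membership columns informative
  about site-level labels.

The defaults (200 proteins of length 60–140, uniform residue background,
roughly balanced classes) were chosen once as the package's reference
conditions. The size is a power decision: pooled out-of-fold AUC over
~1000 fragments has a standard error of about 0.02
(`SE ≈ sqrt((n+1)/(12 n₊ n₋))`), so a chance-level check of 0.5 ± 0.05 is
a ~2.5σ test rather than a coin flip. The uniform background makes the
planted composition signal unambiguous.

What the generator does **not** emulate: realistic kinase motifs, amino
acid background frequencies (an option exists for the motif set only),
homology between proteins, HMM-like smoothness in secondary structure or
disorder (profiles are drawn independently per residue), and the long-tail
sparsity of real annotation vocabularies. Passing the planted-signal
checks therefore demonstrates that the machinery recovers class-conditional
structure it is pointed at — not that a given AUC would transfer to real
phosphoproteome data.

The permutation-null check deserves one note: after label permutation, any
cross-validation run *after* a single global feature selection is
optimistically biased, because the selection has seen the permuted labels
of the held-out folds. `cross_validate(selector = ...)` therefore refits
the entire two-stage selection inside each training fold; only that nested
protocol is expected to sit at AUC ≈ 0.5 under the null.

## Reproducibility and provenance

Every stochastic step (split, fold assignment, forest, generator) takes an
explicit integer seed, and refitting with an identical configuration
reproduces rankings, metrics and reports exactly. `run_pipeline()` embeds a
hash of the effective configuration in every artifact it writes, so
artifacts from different runs cannot be silently combined.

## Known limitations

* The plug-in entropy estimator is biased at small counts; no Miller–Madow
  style correction is applied (deliberately — the selection only uses
  ranks, and all comparisons happen at a fixed sample size).
* Protein-level FF/FA features cannot separate two sites within the same
  protein; they help only insofar as site labels cluster by protein.
* Greedy mRMR is order-dependent by construction; it is the standard
  filter, not an optimal subset search.
* The SVM path is noticeably slower than the forest on wide matrices; for
  exploration start with `algorithm = "rf"`.
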